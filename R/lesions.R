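#' Default (unlesioned) precision configuration
#'
#' All precisions are 1 (no lesion) except the attenuation precision, which
#' defaults to the task's `zeta_att` (0: full suppression of vision during
#' speech, the healthy setting). Each pathway carries the neuromodulator
#' conventionally associated with its precision, for display only:
#' likelihood/attenuation - acetylcholine; transition precision -
#' noradrenaline; policy precision - dopamine; preferences - serotonin.
#'
#' @param task An `"epimem_task"` (for `gamma` and the base `zeta_att`).
#' @return Object of class `"epimem_precision"`: `zeta_att`, `zeta_B_slow`,
#'   `zeta_link_state` (named per linked fast factor), `zeta_link_policy`,
#'   `gamma`, and a `labels` metadata list.
#' @export
default_precision <- function(task) {
  linked <- names(task$link$state)
  structure(list(
    zeta_att = task$config$zeta_att,
    zeta_B_slow = 1,
    zeta_link_state = stats::setNames(rep(1, length(linked)), linked),
    zeta_link_policy = 1,
    gamma = task$config$gamma,
    labels = list(zeta_att = "acetylcholine (likelihood precision)",
                  zeta_B_slow = "noradrenaline (transition precision)",
                  zeta_link_state = "acetylcholine (likelihood precision)",
                  zeta_link_policy = "dopamine (policy precision)",
                  gamma = "dopamine (policy precision)")),
    class = "epimem_precision")
}

#' Specify a computational lesion
#'
#' @param name One of `"encode"`, `"retrieve"`, `"attenuate"`, `"retain"`.
#' @param severity Lesion severity in `[0, 1]` (0 = intact, 1 = maximal).
#'   The package-wide reference severity is 0.8, at which all four
#'   phenotypes separate.
#' @param floor Precision floor the targeted `zeta` is pulled toward as
#'   severity approaches 1 (`zeta' = 1 - severity * (1 - floor)`).
#' @return Object of class `"epimem_lesion"`.
#' @export
lesion_spec <- function(name, severity = 0.8, floor = 0) {
  name <- match.arg(name, c("encode", "retrieve", "attenuate", "retain"))
  if (!is.numeric(severity) || severity < 0 || severity > 1) {
    stop("lesion_spec: severity must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(floor >= 0, floor <= 1)
  structure(list(name = name, severity = severity, floor = floor),
            class = "epimem_lesion")
}

#' Apply a lesion to a precision configuration
#'
#' Scales exactly the pathways the lesion names, leaving every other entry
#' untouched: *encode* reduces the descending/ascending link precisions for
#' initial location, context and policy; *retrieve* reduces them for the
#' semantic slots (knowledge, method, move word, query); *attenuate* raises
#' the attenuation precision toward 1, undoing the suppression of visual
#' input during recall; *retain* reduces the slow-level transition precision
#' on the time-invariant factors, so episode content leaks away between
#' epochs.
#'
#' @param base An `"epimem_precision"`.
#' @param spec An `"epimem_lesion"`.
#' @return A modified copy of `base`.
#' @export
apply_lesion <- function(base, spec) {
  stopifnot(inherits(base, "epimem_precision"), inherits(spec, "epimem_lesion"))
  z <- 1 - spec$severity * (1 - spec$floor)
  out <- base
  switch(spec$name,
    encode = {
      out$zeta_link_state[c("location", "context")] <- z
      out$zeta_link_policy <- z
    },
    retrieve = {
      out$zeta_link_state[c("knowledge", "method", "moveword", "query")] <- z
    },
    attenuate = {
      out$zeta_att <- base$zeta_att + spec$severity * (1 - base$zeta_att)
    },
    retain = {
      out$zeta_B_slow <- z
    })
  out
}
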