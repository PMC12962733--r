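#' @title Generative-model containers
#' @description
#' A fast-level generative model is a plain list of class `"epimem_model"`
#' holding hidden-state factors (with transition tables `B`), sensory
#' modalities (with likelihood tables `A` over a subset of parent factors),
#' log-preferences `C`, initial-state priors `D`, a policy set with prior
#' `E`, and the episode horizon. All tables are dense arrays; each
#' conditional column is a categorical distribution.
#' @name epimem_model
NULL

#' Construct a hidden-state factor
#'
#' @param name Factor name.
#' @param states Character vector of state labels.
#' @param B Transition array, `dim = c(n, n, n_actions)` (next x previous x
#'   action); every (previous, action) column must sum to 1. A matrix is
#'   accepted for uncontrollable factors and promoted to a single-action
#'   array.
#' @param actions Character vector of action labels (`"none"` for
#'   uncontrollable factors).
#' @return A factor description list.
#' @export
make_factor <- function(name, states, B, actions = "none") {
  n <- length(states)
  if (is.matrix(B)) B <- array(B, dim = c(n, n, 1L))
  stopifnot(is.array(B), length(dim(B)) == 3L,
            dim(B)[1] == n, dim(B)[2] == n, dim(B)[3] == length(actions))
  for (a in seq_along(actions)) {
    for (j in seq_len(n)) {
      if (!is_categorical(B[, j, a])) {
        stop(sprintf("factor '%s': B column (state %d, action %s) is not a distribution",
                     name, j, actions[a]), call. = FALSE)
      }
    }
  }
  dimnames(B) <- list(states, states, actions)
  list(name = name, states = states, n = n, B = B, actions = actions,
       controllable = length(actions) > 1L)
}

#' Construct a sensory modality
#'
#' @param name Modality name.
#' @param outcomes Character vector of outcome labels.
#' @param parents Character vector naming the hidden-state factors the
#'   likelihood is conditioned on.
#' @param A Likelihood array, `dim = c(n_outcomes, <parent state counts>)`;
#'   every state-combination column must sum to 1.
#' @return A modality description list.
#' @export
make_modality <- function(name, outcomes, parents, A) {
  n_out <- length(outcomes)
  stopifnot(is.array(A) || is.matrix(A), dim(A)[1] == n_out)
  cols <- matrix(A, nrow = n_out)
  bad <- which(abs(colSums(cols) - 1) > 1e-10 | apply(cols < 0, 2, any))
  if (length(bad)) {
    stop(sprintf("modality '%s': %d likelihood column(s) are not distributions",
                 name, length(bad)), call. = FALSE)
  }
  list(name = name, outcomes = outcomes, n_out = n_out,
       parents = parents, A = A)
}

#' Assemble a fast-level generative model
#'
#' @param factors List of factors from [make_factor()].
#' @param modalities List of modalities from [make_modality()].
#' @param C Named list of log-preference vectors (one per modality; missing
#'   modalities default to flat preferences).
#' @param D Named list of initial-state priors (one categorical per factor).
#' @param policies Integer matrix, `n_policies x (horizon - 1)`, of action
#'   indices for the single controllable factor; row names are policy ids.
#' @param E Categorical prior over policies.
#' @param horizon Number of time-steps per episode.
#' @return An object of class `"epimem_model"`.
#' @export
make_model <- function(factors, modalities, C = list(), D, policies, E,
                       horizon) {
  names(factors) <- vapply(factors, `[[`, "", "name")
  names(modalities) <- vapply(modalities, `[[`, "", "name")
  ctrl <- names(factors)[vapply(factors, `[[`, FALSE, "controllable")]
  if (length(ctrl) > 1L) {
    stop("make_model: at most one controllable factor is supported", call. = FALSE)
  }
  for (m in modalities) {
    missing_parents <- setdiff(m$parents, names(factors))
    if (length(missing_parents)) {
      stop(sprintf("modality '%s' references unknown factor(s): %s",
                   m$name, paste(missing_parents, collapse = ", ")), call. = FALSE)
    }
    expected <- c(m$n_out, vapply(factors[m$parents], `[[`, 0L, "n"))
    if (!identical(as.integer(dim(m$A)), as.integer(expected))) {
      stop(sprintf("modality '%s': A has dim (%s), expected (%s)",
                   m$name, paste(dim(m$A), collapse = ","),
                   paste(expected, collapse = ",")), call. = FALSE)
    }
  }
  for (f in names(factors)) {
    if (is.null(D[[f]]) || length(D[[f]]) != factors[[f]]$n ||
        !is_categorical(D[[f]])) {
      stop(sprintf("make_model: D missing or invalid for factor '%s'", f),
           call. = FALSE)
    }
  }
  full_C <- lapply(modalities, function(m) {
    v <- C[[m$name]]
    if (is.null(v)) v <- numeric(m$n_out)
    if (length(v) != m$n_out || any(!is.finite(v))) {
      stop(sprintf("make_model: C invalid for modality '%s'", m$name),
           call. = FALSE)
    }
    stats::setNames(v, m$outcomes)
  })
  names(full_C) <- names(modalities)
  policies <- as.matrix(policies)
  if (ncol(policies) != horizon - 1L) {
    stop("make_model: policies must supply one action between each pair of steps (horizon - 1 columns)",
         call. = FALSE)
  }
  if (length(ctrl) == 1L) {
    n_act <- length(factors[[ctrl]]$actions)
    if (any(policies < 1L | policies > n_act)) {
      stop("make_model: policy action index out of range", call. = FALSE)
    }
  }
  if (length(E) != nrow(policies) || !is_categorical(E)) {
    stop("make_model: E must be a categorical over the policy set", call. = FALSE)
  }
  structure(list(factors = factors, modalities = modalities, C = full_C,
                 D = D, policies = policies, E = E, horizon = horizon,
                 controllable = if (length(ctrl)) ctrl else NA_character_),
            class = "epimem_model")
}

#' Validate a generative model
#'
#' Re-checks every invariant of an assembled model: all transition and
#' likelihood columns are categorical distributions, priors are valid, the
#' policy set is consistent with the horizon. Intended for models loaded
#' from declarative schema files.
#'
#' @param model An `"epimem_model"` object.
#' @return `model`, invisibly, if valid; otherwise an error describing the
#'   offending table.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "epimem_model"))
  remade <- make_model(model$factors, model$modalities, model$C, model$D,
                       model$policies, model$E, model$horizon)
  invisible(remade)
}

#' @export
print.epimem_model <- function(x, ...) {
  cat("<epimem_model>\n")
  cat(sprintf("  horizon: %d steps, %d policies\n", x$horizon, nrow(x$policies)))
  cat(sprintf("  factors: %s\n", paste(
    sprintf("%s(%d)", names(x$factors),
            vapply(x$factors, `[[`, 0L, "n")), collapse = ", ")))
  cat(sprintf("  modalities: %s\n", paste(
    sprintf("%s(%d)", names(x$modalities),
            vapply(x$modalities, `[[`, 0L, "n_out")), collapse = ", ")))
  invisible(x)
}

## Declarative schema -------------------------------------------------------

#' Load a generative model from a declarative YAML/JSON file
#'
#' The schema mirrors the container structure: `horizon`, a `factors` list
#' (name, states, actions, B as nested lists next x previous x action), a
#' `modalities` list (name, outcomes, parents, A as nested lists), optional
#' `C`, `D`, and a `policies` block (matrix of action labels or indices plus
#' optional prior `E`). Shapes are validated on load with explicit errors,
#' so the built-in task and user-supplied tasks are interchangeable.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `"epimem_model"`.
#' @export
load_model_spec <- function(path) {
  if (!file.exists(path)) stop("load_model_spec: no such file: ", path, call. = FALSE)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  model_from_spec(spec)
}

#' Build a model from an already-parsed declarative specification
#'
#' @param spec Nested list in the schema of [load_model_spec()].
#' @return A validated `"epimem_model"`.
#' @export
model_from_spec <- function(spec) {
  need <- setdiff(c("horizon", "factors", "modalities", "policies"), names(spec))
  if (length(need)) {
    stop("model spec: missing top-level field(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  factors <- lapply(spec$factors, function(f) {
    actions <- if (is.null(f$actions)) "none" else as.character(unlist(f$actions))
    states <- as.character(unlist(f$states))
    n <- length(states)
    B <- if (length(actions) == 1L) {
      # single-action factors may give B as a plain matrix block
      array(.nested_to_array(f$B, c(n, n), sprintf("factor '%s' B", f$name)),
            dim = c(n, n, 1L))
    } else {
      .nested_to_array(f$B, c(n, n, length(actions)),
                       sprintf("factor '%s' B", f$name))
    }
    make_factor(f$name, states, B, actions)
  })
  fnames <- vapply(factors, `[[`, "", "name")
  names(factors) <- fnames
  modalities <- lapply(spec$modalities, function(m) {
    outcomes <- as.character(unlist(m$outcomes))
    parents <- as.character(unlist(m$parents))
    dims <- c(length(outcomes),
              vapply(parents, function(p) {
                if (!p %in% fnames) {
                  stop(sprintf("modality '%s': unknown parent factor '%s'", m$name, p),
                       call. = FALSE)
                }
                factors[[p]]$n
              }, 0L))
    A <- .nested_to_array(m$A, dims, sprintf("modality '%s' A", m$name))
    make_modality(m$name, outcomes, parents, A)
  })
  mnames <- vapply(modalities, `[[`, "", "name")
  names(modalities) <- mnames
  D <- lapply(fnames, function(f) {
    d <- spec$D[[f]]
    if (is.null(d)) rep(1 / factors[[f]]$n, factors[[f]]$n) else as.numeric(unlist(d))
  })
  names(D) <- fnames
  C <- lapply(spec$C, function(v) as.numeric(unlist(v)))
  pol <- spec$policies
  pmat <- do.call(rbind, lapply(pol$actions, function(row) {
    row <- unlist(row)
    ctrl <- fnames[vapply(factors, `[[`, FALSE, "controllable")]
    if (is.character(row)) {
      idx <- match(row, factors[[ctrl]]$actions)
      if (anyNA(idx)) stop("model spec: unknown action label in policies", call. = FALSE)
      idx
    } else as.integer(row)
  }))
  E <- if (is.null(pol$E)) rep(1 / nrow(pmat), nrow(pmat)) else as.numeric(unlist(pol$E))
  make_model(factors, modalities, C, D, pmat, E, as.integer(unlist(spec$horizon)))
}

# Convert nested-list table representations (as parsed from YAML/JSON) into
# a dense array of the expected dimensions, with an explicit shape error.
.nested_to_array <- function(x, dims, what) {
  flat <- tryCatch({
    if (length(dims) == 2L || is.matrix(x)) {
      m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
      as.numeric(m)
    } else {
      # list over the last (slowest) dimension(s), matrices at the bottom
      unlist(.flatten_nested(x, dims), use.names = FALSE)
    }
  }, error = function(e) NULL)
  if (is.null(flat) || length(flat) != prod(dims)) {
    stop(sprintf("%s: expected shape (%s)", what, paste(dims, collapse = ",")),
         call. = FALSE)
  }
  array(flat, dim = dims)
}

.flatten_nested <- function(x, dims) {
  if (length(dims) <= 2L) {
    m <- if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
    if (!identical(as.integer(dim(m)), as.integer(dims[1:2]))) {
      stop("shape mismatch")
    }
    return(as.numeric(m))
  }
  k <- dims[length(dims)]
  if (length(x) != k) stop("shape mismatch")
  lapply(x, .flatten_nested, dims = dims[-length(dims)])
}
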