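#' Construct a generative process (environment)
#'
#' The environment is the world the agent acts on: a set of true hidden
#' states advanced through *true* transition tables and emitting one outcome
#' per modality through *true* likelihood tables. It deliberately reuses the
#' `"epimem_model"` container, so the built-in task's true tables are just a
#' (deterministic) sibling of the agent's model.
#'
#' @param true_model An `"epimem_model"` holding the true A/B tables.
#' @param init_state Named integer vector: true initial state index per
#'   factor.
#' @return An object of class `"epimem_env"`.
#' @export
make_environment <- function(true_model, init_state) {
  fn <- names(true_model$factors)
  if (!all(fn %in% names(init_state))) {
    stop("make_environment: init_state must name every factor", call. = FALSE)
  }
  st <- init_state[fn]
  for (f in fn) {
    if (st[[f]] < 1L || st[[f]] > true_model$factors[[f]]$n) {
      stop(sprintf("make_environment: state index invalid for factor '%s'", f),
           call. = FALSE)
    }
  }
  structure(list(model = true_model, state = st), class = "epimem_env")
}

# Draw from a categorical column: deterministic argmax for one-hot columns
# (the default task), RNG draw otherwise.
.draw <- function(p) {
  if (max(p) >= 1 - 1e-12) return(which.max(p))
  sample.int(length(p), 1L, prob = p)
}

#' Emit one observation from the environment's current state
#'
#' @param env An `"epimem_env"`.
#' @param override Optional named integer vector of outcome indices that
#'   replace the emitted outcome for specific modalities (used to pin the
#'   interview-scene visual stream, and to realize self-generated speech).
#' @return Named integer vector: outcome index per modality.
#' @export
observe_environment <- function(env, override = NULL) {
  m <- env$model
  obs <- vapply(m$modalities, function(mo) {
    # index the likelihood column at the true parent states
    col <- do.call(`[`, c(list(mo$A), list(seq_len(mo$n_out)),
                          as.list(env$state[mo$parents])))
    .draw(as.numeric(col))
  }, 0L)
  names(obs) <- names(m$modalities)
  if (!is.null(override)) {
    obs[names(override)] <- override
  }
  obs
}

#' Advance the environment one step and emit the next observation
#'
#' Advances every true state through its transition table given the action,
#' then emits one outcome per modality. With deterministic tables (the
#' default task) the result is identical for any RNG seed.
#'
#' @param env An `"epimem_env"`.
#' @param action Integer action index for the controllable factor.
#' @param override Passed to [observe_environment()].
#' @return List with elements `env` (advanced environment) and `obs`
#'   (named outcome vector).
#' @export
step_environment <- function(env, action, override = NULL) {
  m <- env$model
  new_state <- env$state
  for (f in names(m$factors)) {
    fac <- m$factors[[f]]
    a <- if (fac$controllable) action else 1L
    if (fac$controllable && (action < 1L || action > length(fac$actions))) {
      stop(sprintf("step_environment: action %d invalid for factor '%s'",
                   action, f), call. = FALSE)
    }
    new_state[[f]] <- .draw(fac$B[, env$state[[f]], a])
  }
  env$state <- new_state
  list(env = env, obs = observe_environment(env, override = override))
}
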