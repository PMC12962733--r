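## Two-timescale linkage.
##
## The slow (episodic) level maintains an exact joint belief over its factors
## (narrative stage, first move, second move, context, query topic) as a
## small dense array. Each slow state combination predicts, through link
## tables, the initial state of fast factors and the fast policy prior
## ("episodic compression": a slow state is a compressed description of a
## fast trajectory). Descending messages turn slow beliefs into fast
## empirical priors; ascending messages turn end-of-epoch fast posteriors
## into soft evidence on the slow joint; slow transitions carry beliefs
## across epochs.

#' Construct a slow-level (episodic) model
#'
#' @param factors List of slow factors from [make_factor()] (single-action
#'   transition tables; the across-epoch dynamics).
#' @param D Named list of initial priors per slow factor.
#' @param n_epochs Number of epochs in the narrative.
#' @param invariant Character vector naming the time-invariant factors (the
#'   compressed episode content); only these are subject to the slow
#'   transition precision `zeta_B_slow`.
#' @return Object of class `"epimem_slow"`.
#' @export
make_slow_model <- function(factors, D, n_epochs, invariant) {
  names(factors) <- vapply(factors, `[[`, "", "name")
  stopifnot(all(invariant %in% names(factors)),
            all(names(factors) %in% names(D)))
  structure(list(factors = factors, D = D, n_epochs = n_epochs,
                 invariant = invariant), class = "epimem_slow")
}

#' Initial slow-level joint belief
#'
#' @param slow_model An `"epimem_slow"`.
#' @return Dense array over all slow factors (outer product of the priors).
#' @export
slow_prior_joint <- function(slow_model) {
  dims <- vapply(slow_model$factors, `[[`, 0L, "n")
  array(Reduce(outer, slow_model$D[names(slow_model$factors)]), dim = dims)
}

#' Per-factor marginals of a slow joint belief
#'
#' @param slow_joint Dense array over the slow factors.
#' @param slow_model An `"epimem_slow"`.
#' @return Named list of categorical marginals.
#' @export
slow_marginals <- function(slow_joint, slow_model) {
  fn <- names(slow_model$factors)
  out <- lapply(seq_along(fn), function(i) {
    stats::setNames(as.numeric(marginalize_joint(slow_joint, i)),
                    slow_model$factors[[i]]$states)
  })
  names(out) <- fn
  out
}

#' Construct a link model
#'
#' @param state_links List of links, each `list(fast_factor, parents, L)`
#'   where `L` has dim `c(n_fast_states, <slow parent state counts>)` and
#'   every slow-state-combination column is a categorical over initial fast
#'   states.
#' @param policy_link `list(parents, L)` with `L` of dim
#'   `c(n_policies, <slow parent state counts>)`, mapping slow state
#'   combinations to a fast policy prior ("what I would do").
#' @return Object of class `"epimem_link"`.
#' @export
make_link <- function(state_links, policy_link) {
  names(state_links) <- vapply(state_links, `[[`, "", "fast_factor")
  for (lk in state_links) {
    cols <- matrix(lk$L, nrow = dim(lk$L)[1])
    if (any(abs(colSums(cols) - 1) > 1e-10)) {
      stop(sprintf("link for '%s': columns must be distributions", lk$fast_factor),
           call. = FALSE)
    }
  }
  structure(list(state = state_links, policy = policy_link),
            class = "epimem_link")
}

# Column-wise precision scaling of a link (or transition) table.
.power_columns <- function(L, zeta) {
  d <- dim(L)
  m <- matrix(L, nrow = d[1])
  m <- apply(m, 2, function(col) apply_precision(col, zeta))
  array(m, dim = d)
}

#' Descending message: slow beliefs to fast empirical priors
#'
#' For each linked fast factor, averages the link columns under the current
#' slow joint belief (exactly, over the joint marginal of the link's slow
#' parents) and applies the corresponding descending precision. Returns the
#' fast initial-state priors and the fast policy prior `E`.
#'
#' @param slow_joint Slow joint belief array.
#' @param slow_model An `"epimem_slow"`.
#' @param link An `"epimem_link"`.
#' @param prec A precision configuration (see [default_precision()]);
#'   `zeta_link_state` entries are per fast factor, `zeta_link_policy`
#'   scales the policy prior.
#' @return List with `D` (named list of fast initial priors) and `E`
#'   (categorical over fast policies).
#' @export
descending_message <- function(slow_joint, slow_model, link, prec) {
  fn <- names(slow_model$factors)
  D <- lapply(link$state, function(lk) {
    par_pos <- match(lk$parents, fn)
    if (anyNA(par_pos)) {
      stop(sprintf("descending_message: link for '%s' names unknown slow factor",
                   lk$fast_factor), call. = FALSE)
    }
    pm <- as.numeric(marginalize_joint(slow_joint, par_pos))
    mixed <- normalize(as.numeric(matrix(lk$L, nrow = dim(lk$L)[1]) %*% pm))
    zeta <- prec$zeta_link_state[[lk$fast_factor]]
    if (is.null(zeta)) zeta <- 1
    apply_precision(mixed, zeta)
  })
  names(D) <- names(link$state)
  pl <- link$policy
  pm <- as.numeric(marginalize_joint(slow_joint, match(pl$parents, fn)))
  E <- apply_precision(normalize(as.numeric(matrix(pl$L, nrow = dim(pl$L)[1]) %*% pm)),
                       prec$zeta_link_policy)
  list(D = D, E = E)
}

#' Ascending message: end-of-epoch fast posteriors to the slow level
#'
#' Each link table is used in the ascending direction with the fast
#' end-of-epoch marginal as soft evidence. To avoid counting the descending
#' empirical prior twice, the evidence passed up is the *net* evidence: the
#' fast posterior divided elementwise by its own descending prior and
#' renormalized (uniform, i.e. uninformative, whenever the epoch supplied no
#' observations about that factor; exact Bayes for one-hot posteriors under
#' a uniform prior). A lesioned precision on a link attenuates its ascending
#' contribution symmetrically: the same table is exponentiated column-wise
#' before use.
#'
#' @param readout Named list of fast posterior marginals at the initial step
#'   of the epoch (smoothed, so static factors carry all within-epoch
#'   evidence), one categorical per linked fast factor.
#' @param q_pi Fast policy posterior at the end of the epoch.
#' @param slow_joint Slow joint belief before assimilation (the epoch's
#'   prior).
#' @param slow_model,link,prec As in [descending_message()].
#' @param fast_priors,E The descending priors the epoch was run with (used
#'   to form net evidence).
#' @return Updated slow joint belief array.
#' @export
ascending_message <- function(readout, q_pi, slow_joint, slow_model, link,
                              prec, fast_priors, E) {
  fn <- names(slow_model$factors)
  dims <- dim(slow_joint)
  post <- slow_joint
  for (lk in link$state) {
    f <- lk$fast_factor
    if (is.null(readout[[f]])) {
      stop(sprintf("ascending_message: no read-out posterior for factor '%s'", f),
           call. = FALSE)
    }
    ratio <- readout[[f]] / fast_priors[[f]]
    ratio[!is.finite(ratio)] <- 0   # states excluded by a deterministic prior
    ratio <- normalize(ratio)
    zeta <- prec$zeta_link_state[[f]]
    if (is.null(zeta)) zeta <- 1
    Lz <- .power_columns(lk$L, zeta)
    ev <- as.numeric(crossprod(matrix(Lz, nrow = dim(Lz)[1]), ratio))
    par_pos <- match(lk$parents, fn)
    post <- post * expand_to_joint(ev, par_pos, dims)
  }
  if (!is.null(q_pi)) {
    pl <- link$policy
    ratio <- q_pi / E
    ratio[!is.finite(ratio)] <- 0
    ratio <- normalize(ratio)
    Lz <- .power_columns(pl$L, prec$zeta_link_policy)
    ev <- as.numeric(crossprod(matrix(Lz, nrow = dim(Lz)[1]), ratio))
    post <- post * expand_to_joint(ev, match(pl$parents, fn), dims)
  }
  s <- sum(post)
  if (s <= 0) {
    stop("ascending_message: fast evidence is inconsistent with the slow prior",
         call. = FALSE)
  }
  post / s
}

#' Slow-level transition to the next epoch
#'
#' Advances the slow joint belief through each factor's across-epoch
#' transition table. The tables of the time-invariant factors are
#' precision-scaled by `zeta_B_slow` (column-wise power and renormalize):
#' at `zeta = 1` beliefs are carried forward essentially unchanged, and as
#' `zeta` falls toward 0 the transition tends to uniform, so information
#' about the episode is lost with each epoch (the failure-to-retain
#' surface). Narrative-stage dynamics are never scaled.
#'
#' @param slow_joint Slow joint belief (the epoch's posterior).
#' @param slow_model An `"epimem_slow"`.
#' @param prec Precision configuration (`zeta_B_slow` is used).
#' @return Joint prior for the next epoch.
#' @export
slow_transition <- function(slow_joint, slow_model, prec) {
  fn <- names(slow_model$factors)
  q <- slow_joint
  for (i in seq_along(fn)) {
    B <- slow_model$factors[[i]]$B[, , 1]
    if (fn[i] %in% slow_model$invariant && prec$zeta_B_slow != 1) {
      B <- matrix(.power_columns(B, prec$zeta_B_slow), nrow = nrow(B))
    }
    q <- contract_factor(q, i, B)
  }
  q / sum(q)
}

#' Run one fast-level epoch (perception-action loop)
#'
#' Executes the full episode: at each step the environment emits an
#' observation (optionally overridden: the interview scene pins vision to
#' the junction view, and during the answer epoch the spoken word is the
#' agent's own most probable predicted utterance, which it then hears); the
#' agent updates exact per-policy state posteriors given all observations so
#' far, scores policies by expected free energy, forms the policy posterior
#' under the descending prior `E`, and selects the next action by marginal
#' argmax.
#'
#' @param model Fast `"epimem_model"` (with epoch-specific `D` and `E`
#'   already in place).
#' @param env `"epimem_env"` for this epoch.
#' @param gamma Policy precision.
#' @param speech_source `"environment"` (scripted question), `"agent"`
#'   (self-generated answer), or `"none"` (no override of speech
#'   modalities).
#' @param pin Named integer vector of outcome overrides applied at every
#'   step (e.g. `c(vision = <junction-view>)` during the interview), or
#'   `NULL`.
#' @return An epoch record: BMA state posteriors (`bma`, factor ->
#'   states x horizon matrix), initial-step smoothed marginals under the
#'   final policy posterior (`readout`), policy posterior trajectory
#'   (`q_pi`, policies x horizon), final policy posterior (`q_pi_final`),
#'   `actions`, `obs`, and the per-policy beliefs of the final step.
#' @export
run_episode <- function(model, env, gamma, speech_source = "none", pin = NULL) {
  Tn <- model$horizon
  n_pol <- nrow(model$policies)
  mnames <- names(model$modalities)
  obs <- matrix(NA_integer_, nrow = length(mnames), ncol = Tn,
                dimnames = list(mnames, NULL))
  q_pi_traj <- matrix(NA_real_, nrow = n_pol, ncol = Tn,
                      dimnames = list(rownames(model$policies), NULL))
  actions <- integer(Tn - 1L)
  bma <- lapply(model$factors, function(f) {
    matrix(0, nrow = f$n, ncol = Tn, dimnames = list(f$states, NULL))
  })
  colH <- lapply(model$modalities, function(m) {
    apply(matrix(m$A, nrow = m$n_out), 2, entropy)
  })
  beliefs <- NULL
  q_pi <- model$E
  for (t in seq_len(Tn)) {
    override <- pin
    if (speech_source == "agent") {
      spoken <- .predicted_word(model, beliefs, q_pi, t)
      override <- c(override, c(audition = spoken, proprioception = spoken))
    }
    obs[, t] <- if (t == 1L) {
      observe_environment(env, override = override)
    } else {
      stepped <- step_environment(env, actions[t - 1L], override = override)
      env <- stepped$env
      stepped$obs
    }
    beliefs <- lapply(seq_len(n_pol), function(p) {
      infer_states(model, model$policies[p, ], obs[, seq_len(t), drop = FALSE])
    })
    G <- vapply(seq_len(n_pol), function(p) {
      expected_free_energy(model, model$policies[p, ], beliefs[[p]],
                           from = t + 1L)
    }, 0)
    # fold the retrospective evidence each policy has earned from the
    # observations into the empirical policy prior ("what I have done"),
    # then weigh prospective expected free energy against it
    logml <- vapply(beliefs, `[[`, 0, "logml")
    E_t <- normalize(model$E * exp(logml - max(logml)))
    q_pi <- policy_posterior(E_t, G, gamma)
    q_pi_traj[, t] <- q_pi
    for (i in seq_along(model$factors)) {
      acc <- 0
      for (p in seq_len(n_pol)) {
        acc <- acc + q_pi[p] * beliefs[[p]]$marginals[[i]][, t]
      }
      bma[[i]][, t] <- acc
    }
    if (t < Tn) actions[t] <- select_action(q_pi, model$policies, t)
  }
  # smoothed full-episode BMA (all observations in hand) for every step,
  # and the initial-step read-out the ascending message uses
  readout <- lapply(seq_along(model$factors), function(i) {
    acc <- 0
    for (p in seq_len(n_pol)) {
      acc <- acc + q_pi[p] * beliefs[[p]]$marginals[[i]][, 1L]
    }
    stats::setNames(acc, model$factors[[i]]$states)
  })
  names(readout) <- names(model$factors)
  smoothed <- lapply(seq_along(model$factors), function(i) {
    acc <- matrix(0, nrow = model$factors[[i]]$n, ncol = Tn,
                  dimnames = list(model$factors[[i]]$states, NULL))
    for (p in seq_len(n_pol)) {
      acc <- acc + q_pi[p] * beliefs[[p]]$marginals[[i]]
    }
    acc
  })
  names(smoothed) <- names(model$factors)
  list(bma = bma, smoothed = smoothed, readout = readout,
       q_pi = q_pi_traj, q_pi_final = q_pi, actions = actions, obs = obs)
}

# Most probable next utterance: BMA posterior-predictive argmax over the
# proprioception outcome at step t given observations up to t - 1.
.predicted_word <- function(model, beliefs, q_pi, t) {
  m <- model$modalities[["proprioception"]]
  if (is.null(m)) stop("speech_source='agent' requires a proprioception modality",
                       call. = FALSE)
  if (is.null(beliefs)) {
    # first step: predict from priors under the prior over policies
    beliefs <- lapply(seq_len(nrow(model$policies)), function(p) {
      infer_states(model, model$policies[p, ], obs = NULL)
    })
  }
  par_pos <- match(m$parents, names(model$factors))
  qo <- 0
  for (p in seq_along(beliefs)) {
    pm <- as.numeric(marginalize_joint(beliefs[[p]]$joint[[t]], par_pos))
    qo <- qo + q_pi[p] * as.numeric(matrix(m$A, nrow = m$n_out) %*% pm)
  }
  which.max(qo)
}
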