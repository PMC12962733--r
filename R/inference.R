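## Exact state inference over a factored hidden-state chain.
##
## The hidden state at each step is the cross-product of all factors; beliefs
## are stored as dense arrays with one dimension per factor (the joint is a
## few thousand cells for the built-in task). Transitions factorize, so a
## one-step prediction is a sequence of per-factor tensor contractions, and
## likelihood evidence enters by broadcasting each modality's column over the
## non-parent dimensions. Smoothing is exact forward-backward on this joint
## chain, conditional on a policy.

joint_dims <- function(model) {
  vapply(model$factors, `[[`, 0L, "n")
}

# Expand an array defined over a subset of dimensions (parents, in their
# A-table order) to the full joint shape, so it can multiply a joint belief.
expand_to_joint <- function(x, parent_pos, dims) {
  K <- length(dims)
  other <- setdiff(seq_len(K), parent_pos)
  arr <- array(as.numeric(x), dim = c(dims[parent_pos], dims[other]))
  # arr currently has dims ordered (parents..., others...); permute back
  perm <- integer(K)
  perm[c(parent_pos, other)] <- seq_len(K)
  aperm(arr, perm)
}

# Marginalize a joint belief array onto a subset of dimensions (in the order
# given by keep_pos, which may be a permutation).
marginalize_joint <- function(q, keep_pos) {
  if (identical(as.integer(keep_pos), seq_along(dim(q)))) return(q)
  apply(q, keep_pos, sum)
}

# Contract a per-factor transition matrix into a joint belief along one axis.
# forward: q'(s_i) = sum_j B[s_i, j] q(j);  backward uses t(B).
contract_factor <- function(q, pos, B) {
  dims <- dim(q)
  K <- length(dims)
  perm <- c(pos, setdiff(seq_len(K), pos))
  m <- matrix(aperm(q, perm), nrow = dims[pos])
  m2 <- B %*% m
  out <- array(m2, dim = dims[perm])
  aperm(out, order(perm))
}

# One-step prediction of a joint belief under a given action index for the
# controllable factor (uncontrollable factors use their single action slice).
predict_joint <- function(model, q, action) {
  fn <- names(model$factors)
  for (i in seq_along(fn)) {
    f <- model$factors[[i]]
    a <- if (f$controllable) action else 1L
    q <- contract_factor(q, i, f$B[, , a])
  }
  q
}

# As predict_joint but propagating a backward message (transposed B).
backpredict_joint <- function(model, q, action) {
  fn <- names(model$factors)
  for (i in seq_along(fn)) {
    f <- model$factors[[i]]
    a <- if (f$controllable) action else 1L
    q <- contract_factor(q, i, t(f$B[, , a]))
  }
  q
}

# Joint likelihood array for the observed modalities at one step.
# obs_step: named integer vector (outcome index per modality, NA = unobserved).
joint_likelihood <- function(model, obs_step) {
  dims <- joint_dims(model)
  lik <- NULL
  for (m in model$modalities) {
    o <- obs_step[[m$name]]
    if (is.null(o) || is.na(o)) next
    if (o < 1L || o > m$n_out) {
      stop(sprintf("observation index %d invalid for modality '%s'", o, m$name),
           call. = FALSE)
    }
    slice <- matrix(m$A, nrow = m$n_out)[o, ]      # over parent combinations
    par_pos <- match(m$parents, names(model$factors))
    ex <- expand_to_joint(slice, par_pos, dims)
    lik <- if (is.null(lik)) ex else lik * ex
  }
  lik
}

#' Infer hidden states under a policy by exact smoothing
#'
#' Computes, for one policy, the exact posterior marginal over every hidden
#' factor at every time-step of the episode, given the observations made so
#' far. Evidence from each observed modality, the forward message through the
#' transition tables from the initial-state priors, and the backward message
#' from later observations are combined by forward-backward smoothing on the
#' joint (all-factor) chain, so the result equals enumeration of
#' `P(s_1..T | o_1..T, policy)` marginals. Steps marked unobserved contribute
#' no likelihood message and yield pure predictions.
#'
#' @param model An `"epimem_model"`.
#' @param policy Integer vector of `horizon - 1` action indices for the
#'   controllable factor, or a single policy row index into `model$policies`.
#' @param obs Integer matrix of outcome indices, one row per modality (row
#'   names must match modality names), one column per time-step; `NA` marks
#'   an unobserved entry. Fewer than `horizon` columns means later steps are
#'   wholly unobserved.
#' @param priors Optional named list of per-factor initial priors
#'   (defaults to `model$D`).
#' @return List with `marginals` (named list: factor -> `n_states x horizon`
#'   matrix of posterior marginals), `joint` (list of `horizon` joint
#'   posterior arrays, used for outcome prediction and expected free
#'   energy), and `logml` (the accumulated log marginal likelihood
#'   `log P(o_1..t | policy)`, the retrospective evidence a policy has
#'   earned from the observations).
#' @export
infer_states <- function(model, policy, obs = NULL, priors = model$D) {
  Tn <- model$horizon
  if (length(policy) == 1L && Tn > 2L) {
    policy <- model$policies[policy, ]
  }
  if (length(policy) != Tn - 1L) {
    stop("infer_states: policy must supply horizon - 1 actions", call. = FALSE)
  }
  dims <- joint_dims(model)
  if (!is.null(obs)) {
    if (is.null(rownames(obs)) ||
        !all(rownames(obs) %in% names(model$modalities))) {
      stop("infer_states: obs rows must be named by modality", call. = FALSE)
    }
    if (ncol(obs) > Tn) {
      stop("infer_states: more observation steps than the horizon", call. = FALSE)
    }
  }
  lik <- vector("list", Tn)
  if (!is.null(obs)) {
    for (t in seq_len(ncol(obs))) {
      # keep the slot even when the step is wholly unobserved (NULL value)
      lik[t] <- list(joint_likelihood(model, obs[, t]))
    }
  }
  prior_joint <- Reduce(function(a, b) outer(a, b), priors[names(model$factors)])
  prior_joint <- array(prior_joint, dim = dims)

  alpha <- vector("list", Tn)
  a <- prior_joint
  if (!is.null(lik[[1]])) a <- a * lik[[1]]
  s <- sum(a)
  if (s <= 0) stop("infer_states: observations have zero probability under the model",
                   call. = FALSE)
  alpha[[1]] <- a / s
  logml <- log(s)
  for (t in seq_len(Tn)[-1]) {
    a <- predict_joint(model, alpha[[t - 1]], policy[t - 1])
    if (!is.null(lik[[t]])) a <- a * lik[[t]]
    s <- sum(a)
    if (s <= 0) stop("infer_states: observations have zero probability under the model",
                     call. = FALSE)
    alpha[[t]] <- a / s
    logml <- logml + log(s)
  }
  beta <- vector("list", Tn)
  beta[[Tn]] <- array(1, dim = dims)
  if (Tn > 1L) {
    for (t in (Tn - 1):1) {
      b <- beta[[t + 1]]
      if (!is.null(lik[[t + 1]])) b <- b * lik[[t + 1]]
      b <- backpredict_joint(model, b, policy[t])
      beta[[t]] <- b / max(b)
    }
  }
  joint <- vector("list", Tn)
  marg <- lapply(model$factors, function(f) {
    matrix(NA_real_, nrow = f$n, ncol = Tn, dimnames = list(f$states, NULL))
  })
  for (t in seq_len(Tn)) {
    g <- alpha[[t]] * beta[[t]]
    g <- g / sum(g)
    joint[[t]] <- g
    for (i in seq_along(model$factors)) {
      marg[[i]][, t] <- as.numeric(marginalize_joint(g, i))
    }
  }
  list(marginals = marg, joint = joint, logml = logml)
}

#' Predicted outcome distributions at one time-step
#'
#' @param model An `"epimem_model"`.
#' @param joint_t Joint posterior array for one time-step (an element of
#'   `infer_states(...)$joint`).
#' @return Named list: modality -> categorical over outcomes.
#' @export
predict_outcomes <- function(model, joint_t) {
  res <- lapply(model$modalities, function(m) {
    par_pos <- match(m$parents, names(model$factors))
    pm <- as.numeric(marginalize_joint(joint_t, par_pos))
    q <- as.numeric(matrix(m$A, nrow = m$n_out) %*% pm)
    stats::setNames(normalize(q), m$outcomes)
  })
  names(res) <- names(model$modalities)
  res
}
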