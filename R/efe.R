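#' Expected free energy of a policy
#'
#' Scores a policy by summing, over the requested future time-steps and all
#' modalities, a risk term and an ambiguity term (natural-log units):
#' risk is the KL divergence from the predicted outcome distribution
#' `Q(o_tau | policy)` to the normalized preference distribution
#' `sigma(C)`, and ambiguity is the expected entropy of the likelihood
#' column under the predicted states. Because risk is measured against a
#' *normalized* preference, it contains a negative predicted-outcome-entropy
#' term, which is what rewards observations expected to disambiguate hidden
#' states (the epistemic, signpost-checking drive).
#'
#' @param model An `"epimem_model"`.
#' @param policy Policy index or action vector (as in [infer_states()]).
#' @param beliefs Result of [infer_states()] for this policy (its `joint`
#'   element is used).
#' @param from First time-step counted as "future" (default 2: everything
#'   after the initial observation).
#' @return Scalar expected free energy `G` (lower is better).
#' @export
expected_free_energy <- function(model, policy, beliefs, from = 2L) {
  Tn <- model$horizon
  if (from > Tn) return(0)
  G <- 0
  pref <- lapply(model$C, softmax)
  colH <- lapply(model$modalities, function(m) {
    cols <- matrix(m$A, nrow = m$n_out)
    apply(cols, 2, entropy)
  })
  for (tau in from:Tn) {
    jt <- beliefs$joint[[tau]]
    for (mi in seq_along(model$modalities)) {
      m <- model$modalities[[mi]]
      par_pos <- match(m$parents, names(model$factors))
      pm <- as.numeric(marginalize_joint(jt, par_pos))
      qo <- normalize(as.numeric(matrix(m$A, nrow = m$n_out) %*% pm))
      risk <- kl_div(qo, pref[[m$name]])
      ambiguity <- sum(pm * colH[[mi]])
      G <- G + risk + ambiguity
    }
  }
  G
}

#' Posterior over policies
#'
#' `softmax(log E - gamma * G)`: the prior over policies `E` (which carries
#' the descending "what I would do" message from the slow level) is combined
#' with the expected free energy of each policy under precision `gamma`.
#' With `gamma = 0` the prior is returned; adding a constant to every `G`
#' entry leaves the posterior unchanged.
#'
#' @param E Categorical prior over policies.
#' @param G Numeric vector of expected free energies, one per policy.
#' @param gamma Policy precision (non-negative scalar).
#' @return Categorical posterior over policies.
#' @export
policy_posterior <- function(E, G, gamma) {
  if (length(E) != length(G)) {
    stop("policy_posterior: E and G must have the same length", call. = FALSE)
  }
  stopifnot(gamma >= 0)
  softmax(log(E) - gamma * G)
}

#' Select the action at one time-step
#'
#' Marginalizes the policy posterior onto the action taken between steps
#' `t` and `t + 1` and returns the most probable action index. Ties are
#' broken deterministically in favour of the lowest action index, so runs
#' with deterministic tables are seed-independent.
#'
#' @param q_pi Categorical posterior over policies.
#' @param policies Policy matrix (`n_policies x (horizon - 1)` action
#'   indices).
#' @param t Time-step index (action taken between `t` and `t + 1`);
#'   must be at most `horizon - 1`.
#' @return Integer action index for the controllable factor.
#' @export
select_action <- function(q_pi, policies, t) {
  policies <- as.matrix(policies)
  if (nrow(policies) == 0L) stop("select_action: empty policy set", call. = FALSE)
  if (t < 1L || t > ncol(policies)) {
    stop("select_action: t outside the action range of the policies", call. = FALSE)
  }
  acts <- policies[, t]
  n_act <- max(acts)
  mass <- vapply(seq_len(n_act), function(a) sum(q_pi[acts == a]), 0)
  which.max(mass)   # which.max already breaks ties at the lowest index
}
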