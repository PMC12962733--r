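test_that("risk vanishes when predictions equal preferences, ambiguity when likelihoods are deterministic", {
  # deterministic (identity) likelihood: ambiguity is exactly zero, and
  # with preferences matching the predicted outcomes the risk is zero too
  m <- tiny_model(A = diag(2), B = matrix(0.5, 2, 2), D = c(0.5, 0.5),
                  C = log(c(0.5, 0.5)), horizon = 2L)
  expect_equal(expected_free_energy(m, 1L, infer_states(m, 1L)), 0,
               tolerance = 1e-12)
})

test_that("one-step KL example: uniform prediction against 0.8/0.2 preference", {
  m <- tiny_model(A = diag(2), B = matrix(0.5, 2, 2), D = c(0.5, 0.5),
                  C = log(c(0.8, 0.2)), horizon = 2L)
  G <- expected_free_energy(m, 1L, infer_states(m, 1L))
  expect_equal(G, 0.5 * log(0.5 / 0.8) + 0.5 * log(0.5 / 0.2),
               tolerance = 1e-12)
  expect_equal(round(G, 4), 0.2231)
})

test_that("ambiguity equals the expected likelihood-column entropy", {
  A <- rbind(c(0.7, 0.5), c(0.3, 0.5))
  m <- tiny_model(A = A, B = diag(2), D = c(0.4, 0.6),
                  C = NULL, horizon = 2L)
  bel <- infer_states(m, 1L)
  G <- expected_free_energy(m, 1L, bel)
  qs <- as.numeric(bel$marginals$s[, 2])
  qo <- as.numeric(A %*% qs)
  byhand <- kl_div(qo, c(0.5, 0.5)) +
    sum(qs * apply(A, 2, function(col) -sum(col * log(col))))
  expect_equal(G, byhand, tolerance = 1e-12)
})

test_that("expected free energy is non-negative with full-support preferences", {
  for (seed in 101:112) {
    m <- random_model(seed)
    set.seed(seed)
    for (mod in names(m$modalities)) {
      m$C[[mod]][] <- runif(length(m$C[[mod]]), -2, 2)
    }
    for (p in seq_len(nrow(m$policies))) {
      G <- expected_free_energy(m, m$policies[p, ], infer_states(m, m$policies[p, ]))
      expect_gte(G, -1e-12)
    }
  }
})

test_that("policy posterior: softmax combination, prior-only limit, shift invariance", {
  E <- c(0.5, 0.5)
  expect_equal(policy_posterior(E, c(1, 2), 1),
               softmax(c(-1, -2)))
  expect_equal(round(policy_posterior(E, c(1, 2), 1), 3), c(0.731, 0.269))
  # gamma = 0: prior returned whatever G is
  expect_equal(policy_posterior(c(0.9, 0.1), c(5, -3), 0), c(0.9, 0.1))
  # equal G entries: prior returned
  expect_equal(policy_posterior(c(0.7, 0.3), c(2, 2), 16), c(0.7, 0.3))
  # adding a constant to G changes nothing
  q1 <- policy_posterior(c(0.2, 0.3, 0.5), c(1, 0, 2), 4)
  q2 <- policy_posterior(c(0.2, 0.3, 0.5), c(1, 0, 2) + 17.3, 4)
  expect_equal(q1, q2, tolerance = 1e-12)
  expect_error(policy_posterior(c(1, 0), c(1, 2, 3), 1), "length")
})

test_that("action selection marginalizes the policy posterior with low-index tie-breaks", {
  pol <- rbind(c(2L, 1L), c(4L, 1L), c(2L, 1L))
  # unanimity at t = 2
  expect_equal(select_action(c(0.2, 0.5, 0.3), pol, 2L), 1L)
  # marginal argmax at t = 1: action 2 carries 0.5, action 4 carries 0.5 ->
  # exact tie broken toward the lower action index
  expect_equal(select_action(c(0.25, 0.5, 0.25), pol, 1L), 2L)
  # clear winner
  expect_equal(select_action(c(0.1, 0.731, 0.169), pol, 1L), 4L)
  expect_error(select_action(numeric(0), pol[0, , drop = FALSE], 1L), "empty")
  expect_error(select_action(c(1), matrix(1L, 1, 1), 2L), "outside")
})
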