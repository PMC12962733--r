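test_that("single-step Bayes: likelihood evidence combines with the prior", {
  m <- tiny_model(A = rbind(c(0.9, 0.3), c(0.1, 0.7)), horizon = 2L)
  obs <- matrix(c(1L, NA), nrow = 1, dimnames = list("o", NULL))
  res <- infer_states(m, 1L, obs[, 1, drop = FALSE])
  expect_equal(as.numeric(res$marginals$s[, 1]), c(0.75, 0.25), tolerance = 1e-10)
})

test_that("a delta likelihood pins the posterior to the observed state", {
  m <- tiny_model(A = diag(2), horizon = 2L)
  obs <- matrix(2L, nrow = 1, dimnames = list("o", NULL))
  res <- infer_states(m, 1L, obs)
  expect_equal(as.numeric(res$marginals$s[, 1]), c(0, 1))
})

test_that("without observations the posterior is the pure transition prediction", {
  M <- rbind(c(0, 1), c(1, 0))   # deterministic swap
  p <- c(0.3, 0.7)
  m <- tiny_model(B = M, D = p, horizon = 2L)
  res <- infer_states(m, 1L, obs = NULL)
  expect_equal(as.numeric(res$marginals$s[, 1]), p)
  expect_equal(as.numeric(res$marginals$s[, 2]), as.numeric(M %*% p))
})

test_that("later observations propagate backwards through smoothing", {
  # identity dynamics: an observation at t = 2 must sharpen beliefs at t = 1
  m <- tiny_model(A = rbind(c(0.9, 0.3), c(0.1, 0.7)), horizon = 2L)
  obs <- matrix(c(NA, 1L), nrow = 1, dimnames = list("o", NULL))
  res <- infer_states(m, 1L, obs)
  expect_equal(as.numeric(res$marginals$s[, 1]), c(0.75, 0.25), tolerance = 1e-10)
})

test_that("smoothing marginals match brute-force enumeration on random tiny models", {
  for (seed in 1:30) {
    m <- random_model(seed)
    obs <- random_obs(m, seed)
    pol <- m$policies[sample(nrow(m$policies), 1), , drop = TRUE]
    res <- infer_states(m, pol, obs)
    oracle <- brute_force_marginals(m, pol, obs)
    for (f in names(oracle)) {
      expect_lt(max(abs(res$marginals[[f]] - oracle[[f]])), 1e-6)
    }
  }
})

test_that("every inferred marginal is a categorical distribution", {
  for (seed in 31:36) {
    m <- random_model(seed)
    res <- infer_states(m, m$policies[1, ], random_obs(m, seed))
    for (f in names(res$marginals)) {
      expect_true(all(abs(colSums(res$marginals[[f]]) - 1) <= 1e-10))
      expect_true(all(res$marginals[[f]] >= -1e-15))
    }
  }
})

test_that("inference rejects malformed inputs", {
  m <- tiny_model()
  expect_error(infer_states(m, c(1L, 1L)), "horizon")
  bad_obs <- matrix(1L, nrow = 1, dimnames = list("nope", NULL))
  expect_error(infer_states(m, 1L, bad_obs), "modality")
  too_long <- matrix(1L, nrow = 1, ncol = 5, dimnames = list("o", NULL))
  expect_error(infer_states(m, 1L, too_long), "horizon")
  expect_error(infer_states(m, 1L, matrix(9L, 1, 1, dimnames = list("o", NULL))),
               "invalid")
})

test_that("log marginal likelihood matches direct computation", {
  m <- tiny_model(A = rbind(c(0.9, 0.3), c(0.1, 0.7)), horizon = 2L)
  obs <- matrix(c(1L, 1L), nrow = 1, dimnames = list("o", NULL))
  res <- infer_states(m, 1L, obs)
  # identity dynamics: P(o1=1,o2=1) = sum_s D(s) A(1|s)^2
  expect_equal(res$logml, log(0.5 * 0.81 + 0.5 * 0.09), tolerance = 1e-12)
})
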