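# A minimal two-level scaffold: one binary slow factor driving one binary
# fast factor through an identity link, plus a trivial two-policy link.
mini_scaffold <- function(link_softness = 1, D_slow = c(0.5, 0.5),
                          slow_B = diag(2)) {
  slow <- make_slow_model(
    list(make_factor("ctx", c("a", "b"), slow_B)),
    D = list(ctx = D_slow), n_epochs = 2L, invariant = "ctx")
  Lf <- if (link_softness == 1) diag(2) else {
    cbind(soft_col2(1, link_softness), soft_col2(2, link_softness))
  }
  link <- make_link(
    state_links = list(list(fast_factor = "f", parents = "ctx", L = Lf)),
    policy_link = list(parents = "ctx", L = matrix(0.5, 2, 2)))
  list(slow = slow, link = link)
}
soft_col2 <- function(i, s) { v <- c(1 - s, 1 - s); v[i] <- s; normalize(v) }
mini_prec <- function(zeta_f = 1, zeta_pol = 1, zeta_B = 1) {
  structure(list(zeta_att = 0, zeta_B_slow = zeta_B,
                 zeta_link_state = c(f = zeta_f), zeta_link_policy = zeta_pol,
                 gamma = 16), class = "epimem_precision")
}

test_that("descending message mixes link columns under the slow belief", {
  sc <- mini_scaffold()
  # one-hot slow belief, zeta = 1: the corresponding link column unchanged
  sj <- array(c(1, 0), dim = 2)
  down <- descending_message(sj, sc$slow, sc$link, mini_prec())
  expect_equal(as.numeric(down$D$f), c(1, 0))
  # graded slow belief through an identity link: matrix-vector product
  sj <- array(c(0.9, 0.1), dim = 2)
  down <- descending_message(sj, sc$slow, sc$link, mini_prec())
  expect_equal(as.numeric(down$D$f), c(0.9, 0.1))
  # zeta = 0: uniform fast prior regardless of the slow belief
  down0 <- descending_message(sj, sc$slow, sc$link, mini_prec(zeta_f = 0))
  expect_equal(as.numeric(down0$D$f), c(0.5, 0.5))
  # policy prior: mixture of the policy link columns
  expect_equal(as.numeric(down$E), c(0.5, 0.5))
})

test_that("ascending message treats fast marginals as soft evidence", {
  sc <- mini_scaffold()
  prec <- mini_prec()
  sj <- array(c(0.5, 0.5), dim = 2)
  priors <- list(f = c(0.5, 0.5))
  E <- c(0.5, 0.5)
  # identity link, uniform slow prior, fast posterior [0.9, 0.1]
  up <- ascending_message(list(f = c(0.9, 0.1)), NULL, sj, sc$slow, sc$link,
                          prec, priors, E)
  expect_equal(as.numeric(up), c(0.9, 0.1))
  # uniform fast posterior: slow belief unchanged
  sj2 <- array(c(0.3, 0.7), dim = 2)
  up2 <- ascending_message(list(f = c(0.5, 0.5)), NULL, sj2, sc$slow, sc$link,
                           prec, priors, E)
  expect_equal(as.numeric(up2), c(0.3, 0.7))
  # zeta = 0 on the pathway: contributes nothing
  up3 <- ascending_message(list(f = c(0.99, 0.01)), NULL, sj2, sc$slow, sc$link,
                           mini_prec(zeta_f = 0), priors, E)
  expect_equal(as.numeric(up3), c(0.3, 0.7))
  # net evidence: a posterior that merely restates its descending prior
  # carries no information upward
  up4 <- ascending_message(list(f = c(0.8, 0.2)), NULL, sj2, sc$slow, sc$link,
                           prec, fast_priors = list(f = c(0.8, 0.2)), E)
  expect_equal(as.numeric(up4), c(0.3, 0.7))
})

test_that("descending then ascending round-trips a one-hot slow belief exactly", {
  sc <- mini_scaffold()   # deterministic identity link
  prec <- mini_prec()
  sj <- array(c(0, 1), dim = 2)
  down <- descending_message(sj, sc$slow, sc$link, prec)
  up <- ascending_message(list(f = down$D$f), down$E, sj, sc$slow, sc$link,
                          prec, fast_priors = list(f = c(0.5, 0.5)),
                          E = c(0.5, 0.5))
  expect_equal(as.numeric(up), c(0, 1))
})

test_that("slow transitions carry, flatten, and lose information as specified", {
  prec1 <- mini_prec(zeta_B = 1)
  sc <- mini_scaffold()
  p <- array(c(0.8, 0.2), dim = 2)
  # identity B at zeta = 1: beliefs carried forward unchanged
  expect_equal(as.numeric(slow_transition(p, sc$slow, prec1)), c(0.8, 0.2))
  # zeta = 0: uniform regardless of the posterior
  expect_equal(as.numeric(slow_transition(p, sc$slow, mini_prec(zeta_B = 0))),
               c(0.5, 0.5))
  # intermediate zeta on a softened-identity table: matrix-vector product
  # against the independently precision-scaled columns
  Bsoft <- cbind(c(0.99, 0.01), c(0.01, 0.99))
  sc2 <- mini_scaffold(slow_B = Bsoft)
  z <- 0.2
  Bles <- apply(Bsoft, 2, function(col) apply_precision(col, z))
  got <- slow_transition(array(c(1, 0), dim = 2), sc2$slow, mini_prec(zeta_B = z))
  expect_equal(as.numeric(got), as.numeric(Bles %*% c(1, 0)), tolerance = 1e-12)
  # and the flattening is strictly monotone in zeta
  diag_mass <- vapply(c(1, 0.6, 0.3, 0), function(zz) {
    slow_transition(array(c(1, 0), dim = 2), sc2$slow, mini_prec(zeta_B = zz))[1]
  }, 0)
  expect_true(all(diff(diag_mass) < 0))
})

test_that("narrative runs are deterministic and bit-identical across repeats", {
  task <- build_task()
  r1 <- run_narrative(task, seed = 1L)
  r2 <- run_narrative(task, seed = 1L)
  expect_identical(r1$epochs[[1]]$actions, r2$epochs[[1]]$actions)
  expect_identical(r1$epochs[[3]]$obs, r2$epochs[[3]]$obs)
  expect_equal(r1$slow, r2$slow, tolerance = 0)
  # different seed, deterministic tables: same trajectory
  r3 <- run_narrative(task, seed = 424242L)
  expect_identical(r1$epochs[[1]]$actions, r3$epochs[[1]]$actions)
  expect_identical(vapply(r1$epochs, function(e) paste(e$transcript, collapse = " "), ""),
                   vapply(r3$epochs, function(e) paste(e$transcript, collapse = " "), ""))
})

test_that("the healthy narrative walks to the signpost, answers, and replays", {
  res <- condition_run("healthy")
  rec <- res$record
  acts <- rec$epochs[[1]]$actions
  # junction -> signpost -> right path (then stay at the absorbing end)
  expect_equal(acts[1:2], c(2L, 4L))
  expect_true(all(acts[3:9] == 1L))
  # the final epoch answers the posed question
  expect_true(res$summary$qa_match)
  # replay: the first three steps of epochs 2 and 3 reproduce the walk
  ref <- apply(rec$epochs[[1]]$smoothed$location[, 1:3], 2, which.max)
  expect_equal(ref, c(1L, 2L, 4L))   # junction, signpost, right-end
  for (e in 2:3) {
    expect_equal(apply(rec$epochs[[e]]$smoothed$location[, 1:3], 2, which.max), ref)
  }
})

test_that("fully certain descending priors with deterministic dynamics yield zero-entropy fast beliefs", {
  # one slow state, deterministic link to a two-state fast chain with
  # deterministic dynamics and a delta likelihood: every fast posterior is
  # one-hot at every step
  f <- make_factor("s", c("x", "y"), rbind(c(0, 1), c(1, 0)))
  mo <- make_modality("o", c("ox", "oy"), "s", array(diag(2), dim = c(2, 2)))
  m <- make_model(list(f), list(mo), list(), list(s = c(1, 0)),
                  policies = matrix(1L, 1L, 3L), E = 1, horizon = 4L)
  env <- make_environment(m, c(s = 1L))
  ep <- run_episode(m, env, gamma = 16)
  expect_true(all(apply(ep$bma$s, 2, max) > 1 - 1e-10))
  expect_true(all(vapply(seq_len(4), function(t) entropy(ep$bma$s[, t]), 0) < 1e-10))
})
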