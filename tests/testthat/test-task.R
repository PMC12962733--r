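test_that("the task bundle has the advertised structure", {
  task <- build_task()
  m <- task$fast_model
  expect_s3_class(m, "epimem_model")
  expect_identical(m$horizon, 10L)
  expect_length(m$modalities, 4L)
  expect_setequal(names(m$modalities),
                  c("vision", "feedback", "audition", "proprioception"))
  expect_identical(nrow(m$policies), 4L)
  expect_identical(ncol(m$policies), 9L)
  # the answer syntax chain has 10 positions, the episode horizon
  expect_length(grep("^A", m$factors$syntax$states), 10L)
  # lexicon covers every speech outcome
  expect_setequal(m$modalities$audition$outcomes, task$lexicon)
  expect_no_error(validate_model(m))
})

test_that("vision is ambiguous at the junction and revealing at the signpost", {
  task <- build_task()
  A <- task$fast_model$modalities$vision$A
  syn_ns <- match("no-speech", task$fast_model$factors$syntax$states)
  # junction view is identical under both contexts
  expect_equal(A[, 1, 1, syn_ns], A[, 1, 2, syn_ns])
  # the signpost column peaks on the context-matching cue
  expect_equal(which.max(A[, 2, 1, syn_ns]), 2L)   # signpost-left
  expect_equal(which.max(A[, 2, 2, syn_ns]), 3L)   # signpost-right
})

test_that("feedback at a path end reflects the true context", {
  task <- build_task()
  A <- task$fast_model$modalities$feedback$A
  syn_ns <- match("no-speech", task$fast_model$factors$syntax$states)
  # right-end, context right -> home; context left -> flooded
  expect_equal(which.max(A[, 4, 2, syn_ns]), 2L)
  expect_equal(which.max(A[, 4, 1, syn_ns]), 3L)
})

test_that("attenuation flattens visual columns during speech only", {
  expect_equal(unname(attenuation_map("no-speech")[c("vision", "feedback")]),
               c(1, 1))
  expect_equal(unname(attenuation_map("A3", zeta_att = 0)[["vision"]]), 0)
  expect_equal(unname(attenuation_map("Q2", zeta_att = 0.8)[["vision"]]), 0.8)
  expect_error(attenuation_map("Z9"), "unknown")
  task <- build_task()   # zeta_att = 0
  A <- task$fast_model$modalities$vision$A
  syn_ans <- match("A2", task$fast_model$factors$syntax$states)
  expect_true(all(abs(A[, , , syn_ans] - 0.2) < 1e-12))
  # with partial attenuation the columns are flattened but not uniform
  m2 <- task$make_fast(0.8)
  expect_true(max(m2$modalities$vision$A[, 1, 1, syn_ans]) < max(A[, 1, 1, 1]))
  expect_gt(max(m2$modalities$vision$A[, 1, 1, syn_ans]), 0.2)
})

test_that("signpost-first policies win under an uncertain context; the known arm wins otherwise", {
  task <- build_task()
  prec <- default_precision(task)
  down <- descending_message(slow_prior_joint(task$slow_model),
                             task$slow_model, task$link, prec)
  model <- task$fast_model
  model$D[names(down$D)] <- down$D
  env <- task$make_env("walk")
  o1 <- observe_environment(env)
  obs <- matrix(o1, ncol = 1, dimnames = list(names(o1), NULL))
  G_of <- function(m) vapply(1:4, function(p) {
    expected_free_energy(m, m$policies[p, ], infer_states(m, m$policies[p, ], obs))
  }, 0)
  G <- G_of(model)
  expect_lt(max(G[1:2]), min(G[3:4]))   # epistemic foraging
  # one-hot context prior: the correct direct arm has the lowest G
  model2 <- model
  model2$D$context <- c(0, 1)
  G2 <- G_of(model2)
  expect_equal(which.min(G2), 4L)       # "right" policy
  expect_lt(G2[4], G2[2])               # beats checking first
  model3 <- model
  model3$D$context <- c(1, 0)
  expect_equal(which.min(G_of(model3)), 3L)
})

test_that("a healthy walk identifies (first move, second move, context) at the slow level", {
  res <- condition_run("healthy")
  post <- res$record$slow[[1]]$posterior
  expect_equal(unname(which.max(post$move1)), 1L)    # signpost
  expect_equal(unname(which.max(post$move2)), 2L)    # right
  expect_equal(unname(which.max(post$context)), 2L)  # home-right
  expect_gt(post$move1[["signpost"]], 0.7)
  expect_gt(post$move2[["right"]], 0.7)
  expect_gt(post$context[["right"]], 0.9)
})

test_that("transcripts decode outcome words in step order, skipping silence", {
  task <- build_task()
  res <- condition_run("healthy")
  ep2 <- res$record$epochs[[2]]
  expect_equal(decode_transcript(ep2, task$lexicon),
               c("what", "was", "your", "first", "move"))
  ep3 <- res$record$epochs[[3]]
  expect_equal(decode_transcript(ep3, task$lexicon),
               c("I", "didnt-know", "the-route-home", "was", "on-the",
                 "right", "so-I", "checked", "by-going", "back"))
  bad <- ep3
  bad$obs["proprioception", 1] <- 999L
  expect_error(decode_transcript(bad, task$lexicon), "lexicon")
})

test_that("task configuration is validated", {
  expect_error(build_task(list(true_context = "up")), "true_context")
  expect_error(build_task(list(posed_query = "third")), "posed_query")
  expect_error(build_task(list(zeta_att = 2)), "zeta_att")
})
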