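#' Run the full three-epoch narrative (walk, listen, answer)
#'
#' Threads the deep-temporal loop: descending message (slow beliefs to fast
#' empirical priors and policy prior), one fast epoch of perception and
#' action, ascending message (end-of-epoch fast posteriors back to the slow
#' joint), and the slow transition to the next epoch. Epoch 1 is the walk
#' (the environment obeys the true Y-junction dynamics); epoch 2 poses the
#' scripted question; epoch 3 is the self-generated answer, where each word
#' spoken is the agent's most probable predicted utterance, subsequently
#' heard.
#'
#' @param task An `"epimem_task"` from [build_task()].
#' @param prec An `"epimem_precision"` (default: unlesioned).
#' @param seed Integer seed; the default task is fully deterministic, so the
#'   seed only matters for user-supplied stochastic tables.
#' @return Object of class `"epimem_record"`: `epochs` (list of epoch
#'   records, each with a decoded `transcript`), `slow` (per-epoch prior and
#'   posterior slow marginals with entropies), `precision`, `condition`
#'   (filled by [run_condition()]), and the task configuration.
#' @export
run_narrative <- function(task, prec = default_precision(task), seed = 1L) {
  stopifnot(inherits(task, "epimem_task"))
  set.seed(seed)
  fast <- task$make_fast(prec$zeta_att)
  slow <- task$slow_model
  link <- task$link
  sj <- slow_prior_joint(slow)
  stages <- c("walk", "listen", "answer")
  epochs <- vector("list", slow$n_epochs)
  slow_trace <- vector("list", slow$n_epochs)
  for (e in seq_len(slow$n_epochs)) {
    down <- descending_message(sj, slow, link, prec)
    model <- fast
    model$D[names(down$D)] <- down$D
    model$E <- down$E
    env <- task$make_env(stages[e])
    ep <- run_episode(model, env, prec$gamma,
                      speech_source = if (stages[e] == "answer") "agent" else "none")
    ep$transcript <- decode_transcript(ep, task$lexicon)
    ep$fast_priors <- model$D
    ep$E <- model$E
    ep$stage <- stages[e]
    sj_post <- ascending_message(ep$readout, ep$q_pi_final, sj, slow, link,
                                 prec, model$D, model$E)
    prior_m <- slow_marginals(sj, slow)
    post_m <- slow_marginals(sj_post, slow)
    slow_trace[[e]] <- list(
      prior = prior_m, posterior = post_m,
      prior_entropy = vapply(prior_m, entropy, 0),
      posterior_entropy = vapply(post_m, entropy, 0))
    epochs[[e]] <- ep
    if (e < slow$n_epochs) sj <- slow_transition(sj_post, slow, prec)
  }
  structure(list(epochs = epochs, slow = slow_trace, precision = prec,
                 condition = NA_character_, config = task$config,
                 seed = seed),
            class = "epimem_record")
}

#' @export
print.epimem_record <- function(x, ...) {
  cat("<epimem_record>", if (!is.na(x$condition)) paste0("condition: ", x$condition),
      "\n")
  for (e in seq_along(x$epochs)) {
    tr <- paste(x$epochs[[e]]$transcript, collapse = " ")
    cat(sprintf("  epoch %d (%s): %s\n", e, x$epochs[[e]]$stage,
                if (nzchar(tr)) shQuote(tr) else "<silence>"))
  }
  invisible(x)
}
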