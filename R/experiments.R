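## Experiment layer: the five headline conditions (healthy + four lesions),
## phenotype metrics, and machine-readable exports.

.CONDITIONS <- c("healthy", "encode", "retrieve", "attenuate", "retain")

#' Replay fidelity of a narrative record
#'
#' The walk trajectory is re-instantiated ("replayed") at the start of the
#' listening and answering epochs. Fidelity is the fraction of
#' walk-trajectory steps whose most probable location in the epoch-1
#' (end-of-epoch, smoothed) posteriors is matched by the most probable
#' location at the corresponding steps of epochs 2 and 3. The replay window
#' covers the first `N` steps, `N` = number of walk moves + 1. Argmax ties
#' are broken at the lowest state index on both sides, so uniform replay
#' beliefs count as mismatches unless the reference is equally degenerate.
#'
#' @param record An `"epimem_record"` with at least 2 epochs.
#' @return Fraction in `[0, 1]`.
#' @export
replay_fidelity <- function(record) {
  if (length(record$epochs) < 2L) {
    stop("replay_fidelity: record must contain at least 2 epochs", call. = FALSE)
  }
  walk <- record$epochs[[1]]
  n_moves <- sum(walk$actions != 1L)
  N <- n_moves + 1L
  ref <- apply(walk$smoothed$location[, seq_len(N), drop = FALSE], 2, which.max)
  hits <- 0L
  total <- 0L
  for (e in seq_along(record$epochs)[-1]) {
    got <- apply(record$epochs[[e]]$smoothed$location[, seq_len(N), drop = FALSE],
                 2, which.max)
    hits <- hits + sum(got == ref)
    total <- total + N
  }
  hits / total
}

#' First step of the final epoch at which a factor's belief becomes precise
#'
#' @param record An `"epimem_record"`.
#' @param factor Fast factor name (default `"context"`).
#' @param threshold Probability threshold (default 0.9).
#' @return 1-based step index, or `NA_integer_` if the maximum posterior
#'   never exceeds the threshold. Beliefs are those held *at* each step
#'   (conditioned on observations up to that step), so recovery reflects
#'   the moment evidence arrives, not hindsight.
#' @export
detect_recovery_step <- function(record, factor = "context", threshold = 0.9) {
  ep <- record$epochs[[length(record$epochs)]]
  if (is.null(ep$bma[[factor]])) {
    stop("detect_recovery_step: unknown fast factor: ", factor, call. = FALSE)
  }
  mx <- apply(ep$bma[[factor]], 2, max)
  hit <- which(mx > threshold)
  if (length(hit)) hit[1L] else NA_integer_
}

# The answer a fully informed witness would give to the posed question.
.expected_answer <- function(record, task) {
  acts <- c("stay", "go-signpost", "go-left", "go-right")
  moves <- acts[record$epochs[[1]]$actions[record$epochs[[1]]$actions != 1L]]
  first <- if (length(moves) >= 1L) moves[1L] else "stay"
  second <- if (length(moves) >= 2L) moves[2L] else "stay"
  word_of <- c("go-signpost" = "back", "go-left" = "to-the-left",
               "go-right" = "to-the-right", "stay" = "silence")
  q <- task$config$posed_query
  checked_first <- first == "go-signpost"
  knowledge <- if (q == "first") {
    if (checked_first) "didnt-know" else "knew"
  } else "knew"
  method <- if (q == "first" && checked_first) "checked" else "found-it"
  moveword <- word_of[[if (q == "first") first else second]]
  c("I", knowledge, "the-route-home", "was", "on-the",
    task$config$true_context, "so-I", method, "by-going", moveword)
}

#' Phenotype summary of one narrative record
#'
#' @param record An `"epimem_record"`.
#' @param task The `"epimem_task"` it was run on.
#' @return List of class `"epimem_phenotype"`: condition, replay fidelity,
#'   context-recovery step, per-epoch slow prior/posterior entropies,
#'   per-epoch transcripts, and the question-answer match flag (whether the
#'   answer given is the correct answer to the question actually posed).
#' @export
phenotype_summary <- function(record, task) {
  transcripts <- vapply(record$epochs, function(ep) {
    paste(ep$transcript, collapse = " ")
  }, "")
  expected <- paste(.expected_answer(record, task), collapse = " ")
  n_ep <- length(record$epochs)
  structure(list(
    condition = record$condition,
    replay_fidelity = replay_fidelity(record),
    recovery_step = detect_recovery_step(record),
    slow_prior_entropy = do.call(rbind, lapply(record$slow, `[[`, "prior_entropy")),
    slow_posterior_entropy = do.call(rbind, lapply(record$slow, `[[`, "posterior_entropy")),
    transcripts = transcripts,
    answer = transcripts[n_ep],
    expected_answer = expected,
    qa_match = identical(transcripts[n_ep], expected)),
    class = "epimem_phenotype")
}

#' @export
print.epimem_phenotype <- function(x, ...) {
  cat(sprintf("<epimem_phenotype> %s\n", x$condition))
  cat(sprintf("  replay fidelity: %.3f | context recovery step: %s | QA match: %s\n",
              x$replay_fidelity,
              ifelse(is.na(x$recovery_step), "none", x$recovery_step),
              x$qa_match))
  cat(sprintf("  question: '%s'\n  answer:   '%s'\n",
              x$transcripts[2], x$answer))
  invisible(x)
}

#' Run one named condition end to end
#'
#' Builds the task, applies the lesion (if any) at the given severity, runs
#' the three-epoch narrative, and computes the phenotype summary. With
#' `out_dir`, writes the belief rasters (CSV, one row per state, one column
#' per step, matching the usual raster-figure layout), the summary (JSON)
#' and the transcripts (text); with `plot = TRUE` additionally writes a
#' raster plot.
#'
#' @param condition One of `"healthy"`, `"encode"`, `"retrieve"`,
#'   `"attenuate"`, `"retain"`.
#' @param severity Lesion severity (ignored for `"healthy"`); default the
#'   reference severity 0.8.
#' @param seed Integer seed.
#' @param config Task configuration overrides (see [build_task()]).
#' @param out_dir Output directory, or `NULL` for no files.
#' @param plot Whether to also write `raster.pdf` under `out_dir`.
#' @return List with `record` (`"epimem_record"`) and `summary`
#'   (`"epimem_phenotype"`).
#' @export
run_condition <- function(condition, severity = 0.8, seed = 1L,
                          config = list(), out_dir = NULL, plot = FALSE) {
  condition <- match.arg(condition, .CONDITIONS)
  task <- build_task(config)
  prec <- default_precision(task)
  if (condition != "healthy") {
    prec <- apply_lesion(prec, lesion_spec(condition, severity))
  }
  record <- run_narrative(task, prec, seed)
  record$condition <- condition
  summary <- phenotype_summary(record, task)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_record(record, summary, out_dir)
    if (plot) {
      grDevices::pdf(file.path(out_dir, "raster.pdf"), width = 9, height = 7)
      plot_raster(record)
      grDevices::dev.off()
    }
  }
  list(record = record, summary = summary)
}

#' Export a record's rasters and summary to a directory
#'
#' @param record An `"epimem_record"`.
#' @param summary Its `"epimem_phenotype"`.
#' @param out_dir Target directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_record <- function(record, summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (e in seq_along(record$epochs)) {
    m <- do.call(rbind, lapply(names(record$epochs[[e]]$smoothed), function(f) {
      x <- record$epochs[[e]]$smoothed[[f]]
      rownames(x) <- paste(f, rownames(x), sep = ".")
      x
    }))
    colnames(m) <- paste0("step", seq_len(ncol(m)))
    p <- file.path(out_dir, sprintf("raster_epoch%d.csv", e))
    utils::write.csv(m, p)
    paths <- c(paths, p)
  }
  sm <- do.call(rbind, lapply(seq_along(record$slow), function(e) {
    unlist(record$slow[[e]]$posterior)
  }))
  rownames(sm) <- paste0("epoch", seq_along(record$slow))
  p <- file.path(out_dir, "raster_slow.csv")
  utils::write.csv(t(sm), p)
  sj <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    condition = summary$condition,
    replay_fidelity = summary$replay_fidelity,
    recovery_step = if (is.na(summary$recovery_step)) "none" else summary$recovery_step,
    qa_match = summary$qa_match,
    transcripts = as.list(summary$transcripts),
    expected_answer = summary$expected_answer,
    slow_posterior_entropy = summary$slow_posterior_entropy,
    slow_prior_entropy = summary$slow_prior_entropy
  ), sj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sj))
}

#' Plot the belief rasters of a record (figure-style layout)
#'
#' Draws, for each epoch, the concatenated fast-factor posterior raster
#' (rows = states, columns = the 10 steps; 1 = black, 0 = white) with the
#' slow-level posterior above.
#'
#' @param record An `"epimem_record"`.
#' @return Invisibly `NULL`; called for its side effect.
#' @export
plot_raster <- function(record) {
  n_ep <- length(record$epochs)
  op <- graphics::par(mfrow = c(2, n_ep), mar = c(2, 8, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  greys <- grDevices::grey(seq(1, 0, length.out = 128))
  for (e in seq_len(n_ep)) {
    sm <- unlist(record$slow[[e]]$posterior)
    graphics::image(x = 1, y = seq_along(sm), z = matrix(sm, nrow = 1),
                    col = greys, zlim = c(0, 1), axes = FALSE,
                    xlab = "", ylab = "", main = sprintf("slow, epoch %d", e))
    graphics::axis(2, at = seq_along(sm), labels = names(sm), las = 2,
                   cex.axis = 0.5, tick = FALSE)
  }
  for (e in seq_len(n_ep)) {
    m <- do.call(rbind, lapply(names(record$epochs[[e]]$smoothed), function(f) {
      x <- record$epochs[[e]]$smoothed[[f]]
      rownames(x) <- paste(f, rownames(x), sep = ".")
      x
    }))
    graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m)[, rev(seq_len(nrow(m)))],
                    col = greys, zlim = c(0, 1), axes = FALSE,
                    xlab = "step", ylab = "", main = sprintf("fast, epoch %d", e))
    graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)), las = 2,
                   cex.axis = 0.35, tick = FALSE)
    graphics::axis(1, at = seq_len(ncol(m)), cex.axis = 0.6)
  }
  invisible(NULL)
}

#' Run and summarize all five conditions
#'
#' Runs healthy plus the four lesions at the given severity, checks the
#' phenotype-separation property (each lesion shows its own signature and
#' only that), and returns one summary row per condition. If the separation
#' property is violated the table is still produced, with `separation_ok`
#' set to `FALSE` on the offending rows and a warning raised.
#'
#' @param out_dir Optional directory for `summary.csv`, `summary.txt` and
#'   per-condition exports.
#' @param severity Reference lesion severity (default 0.8).
#' @param seed Integer seed.
#' @param config Task configuration overrides.
#' @return `data.frame` with one row per condition.
#' @export
summarize_all <- function(out_dir = NULL, severity = 0.8, seed = 1L,
                          config = list()) {
  runs <- lapply(.CONDITIONS, function(cond) {
    run_condition(cond, severity = severity, seed = seed, config = config,
                  out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, cond))
  })
  names(runs) <- .CONDITIONS
  healthy <- runs$healthy$summary
  ctx_H1 <- function(s) s$slow_posterior_entropy[1, "context"]
  qry_H3 <- function(s) s$slow_prior_entropy[3, "query"]
  sep <- c(
    healthy = healthy$replay_fidelity == 1 && healthy$qa_match,
    encode = ctx_H1(runs$encode$summary) > ctx_H1(healthy) &&
      identical(runs$encode$summary$recovery_step, 6L),
    retrieve = runs$retrieve$summary$replay_fidelity == 1 &&
      !identical(runs$retrieve$summary$answer, healthy$answer),
    attenuate = runs$attenuate$summary$replay_fidelity < 1 &&
      identical(runs$attenuate$summary$answer, healthy$answer),
    retain = qry_H3(runs$retain$summary) > qry_H3(healthy))
  if (!all(sep)) {
    warning("phenotype separation violated for: ",
            paste(names(sep)[!sep], collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    condition = .CONDITIONS,
    severity = c(0, rep(severity, 4)),
    replay_fidelity = vapply(runs, function(r) r$summary$replay_fidelity, 0),
    recovery_step = vapply(runs, function(r) as.integer(r$summary$recovery_step), 0L),
    qa_match = vapply(runs, function(r) r$summary$qa_match, FALSE),
    context_entropy_epoch1 = vapply(runs, function(r) ctx_H1(r$summary), 0),
    query_entropy_epoch3 = vapply(runs, function(r) qry_H3(r$summary), 0),
    answer = vapply(runs, function(r) r$summary$answer, ""),
    separation_ok = sep,
    row.names = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(out_dir, "summary.csv"), row.names = FALSE)
    txt <- c(sprintf("Five-condition phenotype summary (severity %.2f)", severity),
             strrep("-", 60),
             vapply(seq_len(nrow(df)), function(i) {
               sprintf("%-9s fidelity %.2f | recovery %s | match %-5s | '%s'",
                       df$condition[i], df$replay_fidelity[i],
                       ifelse(is.na(df$recovery_step[i]), "none", df$recovery_step[i]),
                       df$qa_match[i], df$answer[i])
             }, ""))
    writeLines(txt, file.path(out_dir, "summary.txt"))
  }
  df
}
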