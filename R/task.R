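## The built-in episodic-memory task.
##
## Fast level: an agent at a Y-junction may return to a signpost (which
## reveals whether home is down the left or right path) or commit to a path;
## path ends are absorbing and yield "home" or "flooded" feedback. A small
## language generates one question syntax ("what was your <first|second>
## move") and one answer syntax ("I <knew|didn't know> the route home was on
## the <left|right>, so I <checked|found it> by going
## <back|to the left|to the right>"), advancing one syntactic state per
## step; the longest chain is 10 states, which fixes the episode horizon.
## Slow level: narrative stage (walk -> listen -> answer) plus time-invariant
## compression factors (first move, second move, context, query topic).

.WORDS <- c("silence", "what", "was", "your", "first", "second", "move",
            "I", "knew", "didnt-know", "the-route-home", "on-the",
            "left", "right", "so-I", "checked", "found-it", "by-going",
            "back", "to-the-left", "to-the-right")

.SYNTAX <- c("no-speech", paste0("Q", 1:5), paste0("A", 1:10), "pause")

# task design constants: table softness (graded lesion dose-response needs
# non-degenerate columns) and the slow-transition identity softening
.SOFT <- list(walk_B = 0.95, vision = 0.98, feedback = 0.98,
              link_spatial = 0.96, link_syntax = 0.98, link_slot = 0.90,
              link_query = 0.70, link_policy = 0.96, slow_identity = 0.99)

#' Per-modality precision multipliers for one syntactic state
#'
#' Encodes the syntax-conditioned sensory attenuation: when no speech is in
#' play, vision (and the homologous feedback channel) maps locations to
#' outcomes precisely; while the question/answer syntaxes (and the ensuing
#' interview pause) are in play, those likelihood columns are flattened by
#' the attenuation precision `zeta_att` (default 0: full suppression, so
#' current visual input cannot constrain recollection). The speech channels
#' are always precise: they predict words during speech and silence
#' otherwise through the table structure itself.
#'
#' @param syntax_state Syntactic state label (one of the built-in task's
#'   states).
#' @param zeta_att Attenuation precision in `[0, 1]`.
#' @return Named numeric vector of precision multipliers per modality.
#' @export
attenuation_map <- function(syntax_state, zeta_att = 0) {
  if (!syntax_state %in% .SYNTAX) {
    stop("attenuation_map: unknown syntax state: ", syntax_state, call. = FALSE)
  }
  speech <- syntax_state != "no-speech"
  c(vision = if (speech) zeta_att else 1,
    feedback = if (speech) zeta_att else 1,
    audition = 1, proprioception = 1)
}

# Base (unattenuated) vision column for one (location, context).
.vision_col <- function(loc, ctx, softness) {
  outcomes <- c("junction-view", "signpost-left", "signpost-right",
                "left-end-view", "right-end-view")
  target <- switch(loc,
    "junction" = "junction-view",
    "signpost" = if (ctx == "left") "signpost-left" else "signpost-right",
    "left-end" = "left-end-view",
    "right-end" = "right-end-view")
  soft_column(match(target, outcomes), length(outcomes), softness)
}

.feedback_col <- function(loc, ctx, softness) {
  outcomes <- c("neutral", "home", "flooded")
  target <- switch(loc,
    "junction" = "neutral",
    "signpost" = "neutral",
    "left-end" = if (ctx == "left") "home" else "flooded",
    "right-end" = if (ctx == "right") "home" else "flooded")
  soft_column(match(target, outcomes), length(outcomes), softness)
}

# Word emitted at one syntactic state given the semantic states ("" = none).
.word_at <- function(syn, knowledge, ctx, method, moveword, query) {
  switch(syn,
    "no-speech" = "silence", "pause" = "silence",
    "Q1" = "what", "Q2" = "was", "Q3" = "your", "Q4" = query, "Q5" = "move",
    "A1" = "I", "A2" = knowledge, "A3" = "the-route-home", "A4" = "was",
    "A5" = "on-the", "A6" = ctx, "A7" = "so-I", "A8" = method,
    "A9" = "by-going", "A10" = moveword)
}

# Location transition mapping (next location given location and action).
.loc_next <- function(loc, act) {
  if (loc %in% c("left-end", "right-end")) return(loc)   # absorbing
  switch(act,
    "stay" = loc,
    "go-signpost" = "signpost",
    "go-left" = "left-end",
    "go-right" = "right-end")
}

.syntax_next <- function(s) {
  if (s %in% c("no-speech", "pause")) return(if (s == "no-speech") "no-speech" else "pause")
  if (s == "Q5" || s == "A10") return("pause")
  idx <- match(s, .SYNTAX)
  .SYNTAX[idx + 1L]
}

# Assemble the factors/modalities shared by the agent model and the true
# process; `softness` entries of 1 give the deterministic true tables.
.build_fast_model <- function(zeta_att, gamma, pref_home, pref_flooded,
                              soft = .SOFT, interview_world = FALSE) {
  locations <- c("junction", "signpost", "left-end", "right-end")
  acts <- c("stay", "go-signpost", "go-left", "go-right")
  ctxs <- c("left", "right")
  B_loc <- array(0, dim = c(4, 4, 4))
  for (a in seq_along(acts)) for (j in seq_along(locations)) {
    tgt <- if (interview_world) locations[j] else .loc_next(locations[j], acts[a])
    B_loc[, j, a] <- soft_column(match(tgt, locations), 4, soft$walk_B)
  }
  f_loc <- make_factor("location", locations, B_loc, acts)
  f_ctx <- make_factor("context", ctxs, diag(2))
  B_syn <- matrix(0, 17, 17)
  for (j in seq_along(.SYNTAX)) {
    B_syn[match(.syntax_next(.SYNTAX[j]), .SYNTAX), j] <- 1
  }
  f_syn <- make_factor("syntax", .SYNTAX, B_syn)
  f_kno <- make_factor("knowledge", c("knew", "didnt-know"), diag(2))
  f_met <- make_factor("method", c("checked", "found-it"), diag(2))
  f_mov <- make_factor("moveword", c("back", "to-the-left", "to-the-right"), diag(3))
  f_qry <- make_factor("query", c("first", "second"), diag(2))
  factors <- list(f_loc, f_ctx, f_syn, f_kno, f_met, f_mov, f_qry)

  A_vis <- array(0, dim = c(5, 4, 2, 17))
  A_fb <- array(0, dim = c(3, 4, 2, 17))
  for (s in seq_along(.SYNTAX)) {
    zv <- attenuation_map(.SYNTAX[s], zeta_att)
    for (l in seq_along(locations)) for (cx in seq_along(ctxs)) {
      vcol <- .vision_col(locations[l], ctxs[cx], soft$vision)
      fcol <- .feedback_col(locations[l], ctxs[cx], soft$feedback)
      if (!interview_world) {
        vcol <- apply_precision(vcol, zv[["vision"]])
        fcol <- apply_precision(fcol, zv[["feedback"]])
      }
      A_vis[, l, cx, s] <- vcol
      A_fb[, l, cx, s] <- fcol
    }
  }
  m_vis <- make_modality("vision",
                         c("junction-view", "signpost-left", "signpost-right",
                           "left-end-view", "right-end-view"),
                         c("location", "context", "syntax"), A_vis)
  m_fb <- make_modality("feedback", c("neutral", "home", "flooded"),
                        c("location", "context", "syntax"), A_fb)

  n_w <- length(.WORDS)
  A_aud <- array(0, dim = c(n_w, 17, 2, 2, 2, 3, 2))
  A_pro <- array(0, dim = c(n_w, 17, 2, 2, 2, 3, 2))
  for (s in seq_len(17)) for (k in 1:2) for (cx in 1:2) for (me in 1:2)
    for (mw in 1:3) for (q in 1:2) {
      w <- .word_at(.SYNTAX[s], f_kno$states[k], ctxs[cx], f_met$states[me],
                    f_mov$states[mw], f_qry$states[q])
      A_aud[match(w, .WORDS), s, k, cx, me, mw, q] <- 1
      wp <- if (grepl("^Q", .SYNTAX[s])) "silence" else w   # others' speech is heard, not spoken
      A_pro[match(wp, .WORDS), s, k, cx, me, mw, q] <- 1
    }
  m_aud <- make_modality("audition", .WORDS,
                         c("syntax", "knowledge", "context", "method",
                           "moveword", "query"), A_aud)
  m_pro <- make_modality("proprioception", .WORDS,
                         c("syntax", "knowledge", "context", "method",
                           "moveword", "query"), A_pro)

  policies <- rbind(
    "signpost-left" = c(2L, 3L, rep(1L, 7)),
    "signpost-right" = c(2L, 4L, rep(1L, 7)),
    "left" = c(3L, rep(1L, 8)),
    "right" = c(4L, rep(1L, 8)))
  D <- list(location = one_hot(1, 4), context = c(0.5, 0.5),
            syntax = one_hot(1, 17), knowledge = c(0.5, 0.5),
            method = c(0.5, 0.5), moveword = rep(1 / 3, 3),
            query = c(0.5, 0.5))
  C <- list(feedback = c(neutral = 0, home = pref_home, flooded = pref_flooded))
  make_model(factors, list(m_vis, m_fb, m_aud, m_pro), C, D, policies,
             rep(0.25, 4), horizon = 10L)
}

.build_slow_model <- function(soft = .SOFT) {
  soft_id <- function(n) {
    B <- sapply(seq_len(n), function(j) soft_column(j, n, soft$slow_identity))
    matrix(B, n, n)
  }
  B_stage <- matrix(0, 3, 3)
  B_stage[2, 1] <- 1; B_stage[3, 2] <- 1; B_stage[3, 3] <- 1
  factors <- list(
    make_factor("stage", c("walk", "listen", "answer"), B_stage),
    make_factor("move1", c("signpost", "left", "right"), soft_id(3)),
    make_factor("move2", c("left", "right", "stay"), soft_id(3)),
    make_factor("context", c("left", "right"), soft_id(2)),
    make_factor("query", c("first", "second"), soft_id(2)))
  D <- list(stage = one_hot(1, 3), move1 = rep(1 / 3, 3),
            move2 = rep(1 / 3, 3), context = c(0.5, 0.5),
            query = c(0.4, 0.6))   # mild recency bias toward the latest move
  make_slow_model(factors, D, n_epochs = 3L,
                  invariant = c("move1", "move2", "context", "query"))
}

.build_link <- function(soft = .SOFT) {
  L_loc <- sapply(1:3, function(s) soft_column(1, 4, soft$link_spatial))
  L_ctx <- sapply(1:2, function(c) soft_column(c, 2, soft$link_spatial))
  L_syn <- sapply(c("no-speech", "Q1", "A1"), function(s) {
    soft_column(match(s, .SYNTAX), 17, soft$link_syntax)
  })
  L_kno <- cbind(soft_column(2, 2, soft$link_slot),   # first -> didnt-know
                 soft_column(1, 2, soft$link_slot))   # second -> knew
  L_met <- cbind(soft_column(1, 2, soft$link_slot),   # first -> checked
                 soft_column(2, 2, soft$link_slot))   # second -> found-it
  L_qry <- cbind(soft_column(1, 2, soft$link_query),
                 soft_column(2, 2, soft$link_query))
  # move-word: the answer reports the queried move; a second move of "stay"
  # (no second move was made) predicts no word in particular
  words_m1 <- c(signpost = "back", left = "to-the-left", right = "to-the-right")
  words_m2 <- c(left = "to-the-left", right = "to-the-right")
  mw_states <- c("back", "to-the-left", "to-the-right")
  L_mw <- array(0, dim = c(3, 2, 3, 3))
  for (m1 in 1:3) for (m2 in 1:3) {
    w1 <- words_m1[[c("signpost", "left", "right")[m1]]]
    L_mw[, 1, m1, m2] <- soft_column(match(w1, mw_states), 3, soft$link_slot)
    m2s <- c("left", "right", "stay")[m2]
    L_mw[, 2, m1, m2] <- if (m2s == "stay") rep(1 / 3, 3) else {
      soft_column(match(words_m2[[m2s]], mw_states), 3, soft$link_slot)
    }
  }
  # policy from the compressed moves: "what I would do"
  L_pi <- array(0, dim = c(4, 3, 3))
  for (m1 in 1:3) for (m2 in 1:3) {
    m1s <- c("signpost", "left", "right")[m1]
    m2s <- c("left", "right", "stay")[m2]
    L_pi[, m1, m2] <- if (m1s == "signpost" && m2s == "left") {
      soft_column(1, 4, soft$link_policy)
    } else if (m1s == "signpost" && m2s == "right") {
      soft_column(2, 4, soft$link_policy)
    } else if (m1s == "left") {
      soft_column(3, 4, soft$link_policy)
    } else if (m1s == "right") {
      soft_column(4, 4, soft$link_policy)
    } else rep(0.25, 4)   # signpost then stay: no matching plan
  }
  make_link(
    state_links = list(
      list(fast_factor = "location", parents = "stage", L = L_loc),
      list(fast_factor = "context", parents = "context", L = L_ctx),
      list(fast_factor = "syntax", parents = "stage", L = L_syn),
      list(fast_factor = "knowledge", parents = "query", L = L_kno),
      list(fast_factor = "method", parents = "query", L = L_met),
      list(fast_factor = "moveword", parents = c("query", "move1", "move2"),
           L = L_mw),
      list(fast_factor = "query", parents = "query", L = L_qry)),
    policy_link = list(parents = c("move1", "move2"), L = L_pi))
}

#' Build the episodic-memory task bundle
#'
#' Assembles everything a narrative run needs: the fast-level generative
#' model (10-step horizon; four modalities; move policies signpost-then-left,
#' signpost-then-right, left, right, padded with stay), the slow episodic
#' model, the link tables compressing the walk into (first move, second
#' move, context) and driving the answer slots from (query, moves, context),
#' the deterministic true-environment tables, and the word lexicon for
#' transcript decoding.
#'
#' @param config Optional list overriding defaults: `gamma` (policy
#'   precision, 16), `zeta_att` (attenuation precision, 0 = full
#'   suppression), `pref_home` (+2 nats), `pref_flooded` (-6 nats),
#'   `true_context` (`"right"`), `posed_query` (`"first"`). The preference
#'   magnitudes are calibrated so that, against the normalized preference
#'   distribution, a certain neutral outcome is less risky than a 50/50
#'   home/flooded gamble: checking the signpost then dominates guessing
#'   whenever the context is uncertain, while a known context makes the
#'   direct path optimal.
#' @return An object of class `"epimem_task"`.
#' @export
build_task <- function(config = list()) {
  cfg <- utils::modifyList(list(gamma = 16, zeta_att = 0, pref_home = 2,
                                pref_flooded = -6, true_context = "right",
                                posed_query = "first"), config)
  if (!cfg$true_context %in% c("left", "right")) {
    stop("build_task: true_context must be 'left' or 'right'", call. = FALSE)
  }
  if (!cfg$posed_query %in% c("first", "second")) {
    stop("build_task: posed_query must be 'first' or 'second'", call. = FALSE)
  }
  if (cfg$gamma < 0 || cfg$zeta_att < 0 || cfg$zeta_att > 1) {
    stop("build_task: gamma must be >= 0 and zeta_att in [0, 1]", call. = FALSE)
  }
  make_fast <- function(zeta_att) {
    .build_fast_model(zeta_att, cfg$gamma, cfg$pref_home, cfg$pref_flooded)
  }
  # deterministic generative process: softness 1 everywhere, no attenuation
  det <- utils::modifyList(.SOFT, list(walk_B = 1, vision = 1, feedback = 1))
  true_walk <- .build_fast_model(1, cfg$gamma, cfg$pref_home, cfg$pref_flooded,
                                 soft = det, interview_world = FALSE)
  true_interview <- .build_fast_model(1, cfg$gamma, cfg$pref_home,
                                      cfg$pref_flooded, soft = det,
                                      interview_world = TRUE)
  make_env <- function(stage) {
    ctx <- match(cfg$true_context, c("left", "right"))
    qry <- match(cfg$posed_query, c("first", "second"))
    init <- c(location = 1L, context = ctx,
              syntax = switch(stage, walk = match("no-speech", .SYNTAX),
                              listen = match("Q1", .SYNTAX),
                              answer = match("A1", .SYNTAX)),
              knowledge = 1L, method = 1L, moveword = 1L, query = qry)
    make_environment(if (stage == "walk") true_walk else true_interview, init)
  }
  structure(list(make_fast = make_fast, fast_model = make_fast(cfg$zeta_att),
                 slow_model = .build_slow_model(), link = .build_link(),
                 make_env = make_env, lexicon = .WORDS, config = cfg),
            class = "epimem_task")
}

#' Decode the words of an epoch into a transcript
#'
#' Maps the spoken (proprioception) outcome at each step -- or, when the
#' agent is silent, the heard (audition) outcome -- to its lexicon word and
#' concatenates the non-silence tokens in step order.
#'
#' @param record An epoch record from [run_episode()] (its `obs` matrix is
#'   used).
#' @param lexicon Character vector of words, in outcome-index order.
#' @return Character vector of tokens (possibly empty).
#' @export
decode_transcript <- function(record, lexicon) {
  obs <- record$obs
  ok <- function(i) !is.na(i) && i >= 1L && i <= length(lexicon)
  idx <- vapply(seq_len(ncol(obs)), function(t) {
    p <- obs["proprioception", t]
    a <- obs["audition", t]
    if (!ok(p) || !ok(a)) {
      stop("decode_transcript: outcome index outside the lexicon", call. = FALSE)
    }
    if (lexicon[p] != "silence") p else a
  }, 0L)
  w <- lexicon[idx]
  w[w != "silence"]
}
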