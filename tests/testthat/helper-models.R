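# Shared fixtures: tiny hand-built models, a random-model generator, and an
# independent brute-force oracle that enumerates every joint state sequence.

# One binary factor, one binary modality; likelihood columns given as a
# 2 x 2 matrix (outcome x state).
tiny_model <- function(A = rbind(c(0.9, 0.3), c(0.1, 0.7)),
                       B = diag(2), D = c(0.5, 0.5),
                       C = NULL, horizon = 2L) {
  f <- make_factor("s", c("s1", "s2"), B)
  m <- make_modality("o", c("o1", "o2"), "s", array(A, dim = c(2, 2)))
  Cl <- if (is.null(C)) list() else list(o = C)
  make_model(list(f), list(m), Cl, list(s = D),
             policies = matrix(1L, 1L, horizon - 1L), E = 1, horizon = horizon)
}

# Random small model: 1-2 factors (first controllable with 2 actions),
# 2-4 states each, 1-2 modalities with random parent sets, horizon 2-4.
random_model <- function(seed) {
  set.seed(seed)
  n_fac <- sample(1:2, 1)
  horizon <- sample(2:4, 1)
  rdist <- function(n) normalize(stats::runif(n, 0.05, 1))
  factors <- lapply(seq_len(n_fac), function(i) {
    n <- sample(2:4, 1)
    n_act <- if (i == 1L) 2L else 1L
    B <- array(0, dim = c(n, n, n_act))
    for (a in seq_len(n_act)) for (j in seq_len(n)) B[, j, a] <- rdist(n)
    make_factor(paste0("f", i), paste0("f", i, "_", seq_len(n)), B,
                actions = if (n_act == 2L) c("a1", "a2") else "none")
  })
  n_mod <- sample(1:2, 1)
  modalities <- lapply(seq_len(n_mod), function(k) {
    parents <- sample(seq_len(n_fac), sample(seq_len(n_fac), 1))
    pd <- vapply(factors[parents], `[[`, 0L, "n")
    n_out <- sample(2:3, 1)
    A <- array(0, dim = c(n_out, pd))
    cols <- matrix(A, nrow = n_out)
    for (j in seq_len(prod(pd))) cols[, j] <- rdist(n_out)
    make_modality(paste0("m", k), paste0("m", k, "_", seq_len(n_out)),
                  paste0("f", parents), array(cols, dim = c(n_out, pd)))
  })
  D <- lapply(factors, function(f) rdist(f$n))
  names(D) <- vapply(factors, `[[`, "", "name")
  n_pol <- sample(1:3, 1)
  policies <- matrix(sample(1:2, n_pol * (horizon - 1L), replace = TRUE),
                     nrow = n_pol)
  make_model(factors, modalities, list(), D, policies,
             rep(1 / n_pol, n_pol), horizon)
}

# Random observation matrix for a model (with some entries unobserved).
random_obs <- function(model, seed, p_obs = 0.7) {
  set.seed(seed + 7919L)
  obs <- matrix(NA_integer_, nrow = length(model$modalities),
                ncol = model$horizon,
                dimnames = list(names(model$modalities), NULL))
  for (m in names(model$modalities)) {
    n_out <- model$modalities[[m]]$n_out
    for (t in seq_len(model$horizon)) {
      if (stats::runif(1) < p_obs) obs[m, t] <- sample.int(n_out, 1)
    }
  }
  obs
}

# Independent oracle: enumerate all joint state sequences and sum.
# Returns per-factor marginal matrices like infer_states()$marginals.
brute_force_marginals <- function(model, policy, obs = NULL) {
  Tn <- model$horizon
  fn <- names(model$factors)
  dims <- vapply(model$factors, `[[`, 0L, "n")
  n_joint <- prod(dims)
  # joint index -> per-factor indices
  fac_idx <- as.matrix(expand.grid(lapply(dims, seq_len)))
  # joint transition per action and joint prior
  Bj <- lapply(seq_len(max(1L, length(model$factors[[1]]$actions))), function(a) {
    M <- matrix(1, n_joint, n_joint)
    for (i in seq_along(fn)) {
      f <- model$factors[[i]]
      ai <- if (f$controllable) a else 1L
      M <- M * f$B[, , ai][cbind(rep(fac_idx[, i], times = n_joint),
                                 rep(fac_idx[, i], each = n_joint))]
    }
    M   # M[next, prev] with next varying fastest
  })
  Dj <- rep(1, n_joint)
  for (i in seq_along(fn)) Dj <- Dj * model$D[[i]][fac_idx[, i]]
  # per-step joint likelihood vectors
  likv <- lapply(seq_len(Tn), function(t) {
    v <- rep(1, n_joint)
    if (!is.null(obs) && t <= ncol(obs)) {
      for (m in model$modalities) {
        o <- obs[m$name, t]
        if (is.na(o)) next
        par_pos <- match(m$parents, fn)
        Amat <- matrix(m$A, nrow = m$n_out)
        col_of <- function(row) {
          # linear index into the parent-combination columns
          sub <- fac_idx[row, par_pos, drop = FALSE]
          pd <- dims[par_pos]
          1L + sum((sub - 1L) * cumprod(c(1L, pd[-length(pd)])))
        }
        v <- v * vapply(seq_len(n_joint), function(r) Amat[o, col_of(r)], 0)
      }
    }
    v
  })
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n_joint)), Tn)))
  P <- Dj[seqs[, 1]] * likv[[1]][seqs[, 1]]
  if (Tn > 1L) for (t in 2:Tn) {
    a <- policy[t - 1L]
    P <- P * Bj[[a]][cbind(seqs[, t], seqs[, t - 1L])] * likv[[t]][seqs[, t]]
  }
  P <- P / sum(P)
  marg <- lapply(seq_along(fn), function(i) {
    m <- matrix(0, nrow = dims[i], ncol = Tn,
                dimnames = list(model$factors[[i]]$states, NULL))
    for (t in seq_len(Tn)) {
      m[, t] <- as.numeric(rowsum(P, fac_idx[seqs[, t], i]))
    }
    m
  })
  names(marg) <- fn
  marg
}

# Memoized condition runs shared across test files (one R session).
.run_cache <- new.env(parent = emptyenv())
condition_run <- function(name, severity = 0.8) {
  key <- paste0(name, "_", severity)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_condition(name, severity = severity, seed = 1L)
  }
  .run_cache[[key]]
}
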