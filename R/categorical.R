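#' Normalize a non-negative vector into a categorical distribution
#'
#' Categorical distributions are the belief currency of the whole package:
#' posteriors over hidden states, policy posteriors, and outcome predictions
#' are all plain numeric vectors (optionally named by state labels) that sum
#' to one.
#'
#' @param v Numeric vector with non-negative entries and at least one
#'   strictly positive entry. Names, if any, are preserved.
#' @return Numeric vector `v / sum(v)`.
#' @examples
#' normalize(c(2, 2))
#' normalize(c(0.45, 0.15))
#' @export
normalize <- function(v) {
  if (!is.numeric(v) || length(v) == 0L) {
    stop("normalize: input must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(v))) {
    stop("normalize: input contains non-finite entries", call. = FALSE)
  }
  if (any(v < 0)) {
    stop("normalize: input contains negative entries", call. = FALSE)
  }
  s <- sum(v)
  if (s <= 0) {
    stop("normalize: degenerate distribution (all entries zero)", call. = FALSE)
  }
  v / s
}

#' Rescale the precision of a categorical distribution
#'
#' Applies temperature-like precision scaling: each probability is raised to
#' the power `zeta` and the result renormalized. `zeta = 1` is the identity,
#' `zeta = 0` gives the uniform distribution (over the support convention
#' `0^0 = 1`, so every outcome becomes equally plausible), and `zeta > 1`
#' sharpens the distribution. This is the single mechanism through which all
#' lesions act: reducing a precision toward zero attenuates the influence one
#' variable's beliefs have on another's.
#'
#' @param d Categorical distribution (numeric vector summing to 1).
#' @param zeta Non-negative finite scalar precision exponent.
#' @return Categorical distribution of the same length (names preserved).
#' @examples
#' apply_precision(c(0.8, 0.2), 2)   # sharpened
#' apply_precision(c(0.8, 0.2), 0)   # uniform
#' @export
apply_precision <- function(d, zeta) {
  stopifnot(is.numeric(d), length(zeta) == 1L, is.finite(zeta), zeta >= 0)
  out <- d^zeta
  # 0^0 is 1 in R, which is exactly the uniform-limit convention we want
  res <- normalize(out)
  names(res) <- names(d)
  res
}

#' Shannon entropy of a categorical distribution (nats)
#'
#' @param p Categorical distribution.
#' @return Entropy in natural-log units; `0 * log(0)` treated as 0.
#' @export
entropy <- function(p) {
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Kullback-Leibler divergence KL(p || q) in nats
#'
#' Terms with `p = 0` contribute zero; `p > 0` where `q = 0` yields `Inf`.
#'
#' @param p,q Categorical distributions of equal length.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
kl_div <- function(p, q) {
  stopifnot(length(p) == length(q))
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(q[nz])))
}

#' Softmax of a vector of log-weights
#'
#' @param x Numeric vector of (finite or -Inf) log-weights.
#' @return Categorical distribution proportional to `exp(x)`.
#' @export
softmax <- function(x) {
  m <- max(x)
  if (!is.finite(m)) stop("softmax: no finite entries", call. = FALSE)
  normalize(exp(x - m))
}

## Internal helpers ---------------------------------------------------------

# Check a vector is a categorical within tolerance; used by validators.
is_categorical <- function(p, tol = 1e-10) {
  is.numeric(p) && all(p >= 0) && abs(sum(p) - 1) <= tol
}

# One-hot vector of length n with mass at index i.
one_hot <- function(i, n) {
  v <- numeric(n)
  v[i] <- 1
  v
}

# Argmax with deterministic tie-breaking at the lowest index.
which_max1 <- function(x) which.max(x)

# Mix the softness eps uniformly off the target entries of a column:
# target entries share (1 - eps), the rest share eps.  Used when building
# mildly soft conditional tables so precision exponents have graded effects.
soft_column <- function(target, n, softness) {
  stopifnot(softness > 0.5, softness <= 1)
  v <- rep((1 - softness) / max(n - length(target), 1L), n)
  v[target] <- softness / length(target)
  normalize(v)
}
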