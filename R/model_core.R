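#' @keywords internal
"_PACKAGE"

# Probability floor used before any logarithm. Saturated categorical beliefs
# (e.g. [1, 0]) would otherwise produce -Inf log-evidence in the belief
# updates, so every probability entering a log is clamped to
# [PROB_EPS, 1 - PROB_EPS].
PROB_EPS <- 1e-6

# Floor for Dirichlet concentration parameters: a degenerate expression policy
# such as [1, 0] scaled by the concentration multiplier would give an invalid
# zero concentration for one component.
CONC_FLOOR <- 1e-3

#' Clamp a probability vector away from 0 and 1
#'
#' Components are clamped to `[1e-6, 1 - 1e-6]` and renormalized to sum to 1.
#' All belief states pass through this before any logarithm is taken, so that
#' saturated beliefs stay finite in log space.
#'
#' @param p Numeric vector of non-negative weights (need not be normalized).
#' @return A probability vector of the same length summing to 1.
#' @export
#' @examples
#' clamp_prob(c(1, 0))
clamp_prob <- function(p) {
  if (!is.numeric(p) || !all(is.finite(p)) || any(p < 0) || sum(p) <= 0) {
    stop("invalid probability weights")
  }
  p <- p / sum(p)
  p <- pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
  p / sum(p)
}

#' Validate a probability vector
#'
#' @param p Numeric vector.
#' @param n Expected length, or `NULL` to skip the length check.
#' @param tol Tolerance on the sum-to-one constraint.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_prob <- function(p, n = NULL, tol = 1e-9) {
  if (!is.numeric(p) || !all(is.finite(p)) || any(p < 0)) {
    stop("invalid probability vector")
  }
  if (!is.null(n) && length(p) != n) {
    stop("probability vector has wrong length")
  }
  if (abs(sum(p) - 1) > tol) {
    stop("probability vector does not sum to 1 (sum = ", sum(p), ")")
  }
  invisible(TRUE)
}

#' Precision-weighted softmax
#'
#' Returns `exp(gamma * logits)` normalized to sum to one. `gamma` plays the
#' role of an inverse temperature (a precision): `gamma = 0` gives the uniform
#' distribution, large `gamma` concentrates mass on the largest logit.
#'
#' @param logits Finite numeric vector of log-weights.
#' @param gamma Non-negative scalar precision. Default 1.
#' @return Probability vector of the same length as `logits`.
#' @export
#' @examples
#' softmax(c(0, -0.368, -0.468))
softmax <- function(logits, gamma = 1) {
  if (!all(is.finite(logits))) {
    stop("non-finite logits passed to softmax(); upstream beliefs were not clamped")
  }
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma < 0) {
    stop("gamma must be a finite non-negative scalar")
  }
  z <- gamma * logits
  z <- z - max(z)  # overflow guard; softmax is shift-invariant
  e <- exp(z)
  e / sum(e)
}

#' Kullback-Leibler divergence between two categorical distributions
#'
#' Computes `sum(p * log(p / q))`, with `0 * log(0) = 0`.
#'
#' @param p,q Probability vectors of equal length; `q` must have strictly
#'   positive components.
#' @return Non-negative scalar; 0 iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  check_prob(p, tol = 1e-6)
  check_prob(q, length(p), tol = 1e-6)
  if (any(q <= 0)) stop("q has a zero component; KL divergence undefined")
  terms <- ifelse(p > 0, p * (log(p) - log(q)), 0)
  sum(terms)
}

#' Shannon entropy of a categorical distribution
#'
#' @param p Probability vector.
#' @return Non-negative scalar in nats.
#' @export
entropy <- function(p) {
  check_prob(p, tol = 1e-6)
  -sum(ifelse(p > 0, p * log(p), 0))
}

#' Sample from a Dirichlet distribution
#'
#' One draw from `Dir(concentration)`, via normalized Gamma variates.
#' Concentrations are floored at `1e-3` so that degenerate inputs (one zero
#' component) still define a valid distribution.
#'
#' @param concentration Non-negative numeric vector, not all zero. Its
#'   normalized value is the mean of the sampled distribution.
#' @return A probability vector.
#' @export
#' @examples
#' set.seed(1)
#' dirichlet_sample(c(6, 6))
dirichlet_sample <- function(concentration) {
  if (!is.numeric(concentration) || !all(is.finite(concentration)) ||
      any(concentration < 0)) {
    stop("invalid Dirichlet concentration")
  }
  if (sum(concentration) == 0) stop("all-zero Dirichlet concentration")
  a <- pmax(concentration, CONC_FLOOR)
  g <- stats::rgamma(length(a), shape = a, rate = 1)
  if (sum(g) == 0) {        # numerically possible for tiny concentrations
    g <- a
  }
  g / sum(g)
}

#' Apply a row-stochastic likelihood map to a state belief
#'
#' `map` has one row per hidden state giving the outcome distribution for that
#' state; applying it to a belief `x` over hidden states marginalizes the
#' hidden state: `o = t(map) %*% x`.
#'
#' @param map Row-stochastic matrix (`n_states` x `n_outcomes`).
#' @param x Probability vector over hidden states (length `nrow(map)`).
#' @return Probability vector over outcomes (length `ncol(map)`).
#' @export
apply_map <- function(map, x) {
  if (!is.matrix(map) || length(x) != nrow(map)) {
    stop("map/state dimension mismatch")
  }
  check_prob(x, tol = 1e-6)
  as.vector(crossprod(map, x))
}

#' Construct a 2x2 row-stochastic map blending identity with uniform
#'
#' `blend = 1` gives the identity mapping (each hidden state deterministically
#' produces its congruent outcome), `blend = 0` the uninformative uniform map.
#' Used for expression likelihoods and confirmation-bias preference maps.
#'
#' @param blend Scalar in `[0, 1]`.
#' @return A 2x2 row-stochastic matrix.
#' @export
#' @examples
#' blend_identity(0.9)
blend_identity <- function(blend) {
  stopifnot(is.numeric(blend), length(blend) == 1, blend >= 0, blend <= 1)
  blend * diag(2) + (1 - blend) * matrix(0.5, 2, 2)
}
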