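# Slow-timescale learning: Dirichlet concentration accumulation.
#
# Two kinds of counts accumulate across meetings and never decrease:
# alpha -- a 2x2 matrix of precision-weighted co-occurrence counts between
# observed expressions (rows: support/oppose) and valence states (columns:
# positive/negative), whose row-normalization is the valence likelihood map;
# and habit counts epsilon for expression (length 2) and visitation
# (length n). Learning changes behavior only across meetings, never within
# one.

#' Accumulate valence-likelihood counts from one observation
#'
#' Adds the precision-weighted outer product of the observed expression and
#' the valence state to the concentration matrix:
#' `alpha' = alpha + gamma_a2 * (o_expr %o% x_sat)`. Since both vectors are
#' normalized, total count mass grows by exactly `gamma_a2` per update.
#'
#' @param alpha 2x2 non-negative count matrix (expression x valence).
#' @param o_expr Observed expression (probability 2-vector).
#' @param x_sat Associated valence (probability 2-vector).
#' @param gamma_a2 Non-negative learning precision.
#' @return Updated 2x2 count matrix.
#' @export
update_valence_likelihood <- function(alpha, o_expr, x_sat, gamma_a2) {
  if (!is.matrix(alpha) || !all(dim(alpha) == 2) || any(alpha < 0) ||
      gamma_a2 < 0) {
    stop("invalid valence-likelihood update inputs")
  }
  check_prob(o_expr, 2, tol = 1e-6)
  check_prob(x_sat, 2, tol = 1e-6)
  alpha + gamma_a2 * (o_expr %o% x_sat)
}

#' Valence likelihood map from concentration counts
#'
#' Dirichlet-mean normalization of each idea-state row, yielding the
#' row-stochastic map used by [infer_valence()]. Invariant to a global
#' rescaling of the counts.
#'
#' @param alpha 2x2 non-negative count matrix with positive row totals.
#' @return 2x2 row-stochastic matrix.
#' @export
counts_to_likelihood <- function(alpha) {
  if (!is.matrix(alpha) || !all(dim(alpha) == 2) || any(alpha < 0)) {
    stop("invalid count matrix")
  }
  rs <- rowSums(alpha)
  if (any(rs <= 0)) stop("zero row total in valence-likelihood counts")
  alpha / rs
}

#' Reinforce a habit count
#'
#' Increments the count of the action taken, leaving all others unchanged.
#'
#' @param counts Non-negative numeric count vector.
#' @param action Index of the action taken.
#' @param increment Non-negative increment (default 1).
#' @return Updated count vector.
#' @export
update_habit <- function(counts, action, increment = 1) {
  if (any(counts < 0) || increment < 0) stop("counts must be non-negative")
  if (action < 1 || action > length(counts)) {
    stop("habit action index out of range")
  }
  counts[action] <- counts[action] + increment
  counts
}

#' Habit prior from counts
#'
#' Dirichlet-mean normalization of the habit counts; invariant to scaling.
#'
#' @param counts Count vector with positive total.
#' @return Probability vector.
#' @export
habit_to_prior <- function(counts) {
  if (any(counts < 0)) stop("negative habit count")
  if (sum(counts) <= 0) stop("zero habit count total")
  counts / sum(counts)
}

#' Record a conversation in the visit memory
#'
#' Sets `last_seen[partner] = day`. The caller records symmetrically for both
#' parties of a conversation.
#'
#' @param last_seen Numeric vector of day indices (`NA` = never seen).
#' @param partner Partner index.
#' @param day Current day index (must not precede an existing entry).
#' @return Updated `last_seen` vector.
#' @export
record_visit <- function(last_seen, partner, day) {
  if (partner < 1 || partner > length(last_seen)) {
    stop("partner index out of range")
  }
  if (!is.na(last_seen[partner]) && day < last_seen[partner]) {
    stop("visit recorded before the most recent one")
  }
  last_seen[partner] <- day
  last_seen
}
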