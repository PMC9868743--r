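# Affect and belief expression.
#
# Emotional valence (positive/negative) is inferred from the core belief via a
# learnable likelihood map; valence sets the rate of a Gamma distribution over
# the expression precision (positive valence -> low rate -> high expected
# precision -> sharp, confident utterances); the expression policy combines
# precision-weighted core belief with expression habits; the emitted
# expression is a Dirichlet draw around the policy.

# Gamma-rate constants associated with positive / negative valence: the
# expression rate is their Bayesian model average under the valence state.
BETA_PLUS <- 0.25
BETA_MINUS <- 2.0

# Concentration multiplier for emitted expressions and affective cues: the
# policy (a probability 2-vector) scaled by 12 gives the Dirichlet
# concentration, keeping draws in (0,1) with moderate variance.
EXPR_CONCENTRATION <- 12

#' Infer emotional valence from the core belief
#'
#' Marginalizes the core belief through the (learnable) valence likelihood
#' map: `x_sat = t(a_sat) %*% x_core`. Index 1 is positive valence.
#'
#' @param core Probability 2-vector over {status quo, alternative}.
#' @param a_sat 2x2 row-stochastic map from idea state to valence.
#' @return Probability 2-vector over {positive, negative} valence.
#' @export
infer_valence <- function(core, a_sat) {
  apply_map(a_sat, clamp_prob(core))
}

#' Expression rate from the valence state
#'
#' Bayesian model average of the rate constants associated with positive and
#' negative valence: `beta_expr = 0.25 * x_sat[pos] + 2.0 * x_sat[neg]`.
#' Bounded in `[0.25, 2.0]` and linear in the valence state.
#'
#' @param x_sat Valence state (probability 2-vector, positive first).
#' @return Scalar rate in `[0.25, 2.0]`.
#' @export
expression_rate <- function(x_sat) {
  check_prob(x_sat, 2, tol = 1e-6)
  BETA_PLUS * x_sat[1] + BETA_MINUS * x_sat[2]
}

#' Sample the expression precision
#'
#' Draw from `Gamma(shape = 1, rate = beta_expr)`, whose mean is
#' `1 / beta_expr`: positive valence (low rate) yields high expected precision
#' and hence confident expression. `deterministic = TRUE` returns the mean,
#' for reproducible unit tests and deterministic experiment modes.
#'
#' @param beta_expr Positive rate parameter.
#' @param deterministic If `TRUE`, return the mean instead of sampling.
#' @return Non-negative scalar precision.
#' @export
sample_expression_precision <- function(beta_expr, deterministic = FALSE) {
  if (!is.numeric(beta_expr) || length(beta_expr) != 1 ||
      !is.finite(beta_expr) || beta_expr <= 0) {
    stop("expression rate must be a positive scalar")
  }
  if (deterministic) return(1 / beta_expr)
  stats::rgamma(1, shape = 1, rate = beta_expr)
}

#' Expression policy from core belief and habit
#'
#' `u_expr = softmax(gamma_expr * ln x_core + gamma_e * E)`, where `E` is the
#' normalized expression-habit prior, a probability vector on (0, 1) entering
#' the softmax directly, so habit contributes a bounded bias of at most
#' `gamma_e` logits. Higher `gamma_expr` sharpens alignment of the expressed
#' claim with the core belief; `gamma_expr = 0` leaves pure habit.
#' `printed_sign = TRUE` flips the sign of the belief term (an alternative
#' convention under which agents express the claim they believe less; kept
#' for comparison, not the default).
#'
#' @param core Core belief (probability 2-vector).
#' @param habit Expression-habit prior (probability 2-vector, e.g. from
#'   [habit_to_prior()]).
#' @param gamma_expr Non-negative expression precision.
#' @param gamma_e Non-negative habit precision (default 1).
#' @param printed_sign Flip the belief-term sign. Default `FALSE`.
#' @return Probability 2-vector over {support claim, deny claim}.
#' @export
expression_policy <- function(core, habit, gamma_expr, gamma_e = 1,
                              printed_sign = FALSE) {
  if (gamma_expr < 0 || gamma_e < 0) stop("precisions must be >= 0")
  check_prob(habit, 2, tol = 1e-6)
  s <- if (printed_sign) -1 else 1
  logit <- s * gamma_expr * log(clamp_prob(core)) + gamma_e * habit
  softmax(logit)
}

#' Emit a noisy expression and affective cue
#'
#' The observed expression is a Dirichlet draw with concentration
#' `12 * u_expr` (mean `u_expr`); the affective cue is a Dirichlet draw with
#' concentration `12 * x_sat`, conditioned on the current valence state.
#' `deterministic = TRUE` returns the means.
#'
#' @param u_expr Expression policy (probability 2-vector).
#' @param x_sat Valence state (probability 2-vector).
#' @param deterministic If `TRUE`, return Dirichlet means instead of draws.
#' @return List with components `o_expr` and `o_affect`, both probability
#'   2-vectors in (0, 1).
#' @export
emit_expression <- function(u_expr, x_sat, deterministic = FALSE) {
  check_prob(u_expr, 2, tol = 1e-6)
  check_prob(x_sat, 2, tol = 1e-6)
  if (deterministic) {
    return(list(o_expr = u_expr, o_affect = x_sat))
  }
  list(o_expr = dirichlet_sample(EXPR_CONCENTRATION * u_expr),
       o_affect = dirichlet_sample(EXPR_CONCENTRATION * x_sat))
}
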