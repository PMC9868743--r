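# Perceptual inference: within- and across-meeting belief updating.
#
# An agent's core belief over the binary idea {status quo, alternative} is a
# categorical distribution. Across meetings it decays toward uniform under a
# volatility kernel (the transition map B); within a meeting the agent adopts
# the partner's observed expression as its posterior about the partner's idea
# state, and updates its own core belief from the log-evidence carried by its
# own and the partner's expressions, weighted by likelihood precisions.

#' Volatility kernel for belief decay
#'
#' A symmetric 2-state transition with switch probability `switch_prob` in
#' `[0, 0.5]`. Repeated application contracts any belief geometrically toward
#' uniform at rate `1 - 2 * switch_prob` (in the deviation-from-uniform sense),
#' modeling a prior that states may change between meetings.
#'
#' @param switch_prob Scalar in `[0, 0.5]`.
#' @return An object of class `volatility_kernel` (a validated scalar).
#' @export
volatility_kernel <- function(switch_prob) {
  stopifnot(is.numeric(switch_prob), length(switch_prob) == 1,
            is.finite(switch_prob), switch_prob >= 0, switch_prob <= 0.5)
  structure(switch_prob, class = "volatility_kernel")
}

#' Switch probability from a transition precision
#'
#' Maps a non-negative precision on the transition map to a switch probability
#' `v = 0.5 / (1 + gamma_B)`: infinite precision means no decay, zero
#' precision means full mixing to uniform in one step. The decay rate is thus
#' inversely related to the precision of the transition model.
#'
#' @param gamma_b Non-negative scalar precision.
#' @return A [volatility_kernel].
#' @export
kernel_from_precision <- function(gamma_b) {
  stopifnot(is.numeric(gamma_b), length(gamma_b) == 1, is.finite(gamma_b),
            gamma_b >= 0)
  volatility_kernel(0.5 / (1 + gamma_b))
}

#' Initialize a core belief from a prior
#'
#' The initial core belief equals the prior D, clamped away from saturation.
#'
#' @param prior Probability 2-vector (status-quo support first).
#' @return A clamped probability 2-vector.
#' @export
init_core_belief <- function(prior) {
  stopifnot(length(prior) == 2)
  clamp_prob(prior)
}

#' Decay a belief toward uniform under a volatility kernel
#'
#' One application of the symmetric transition: `b' = [b1 (1-v) + b2 v,
#' b1 v + b2 (1-v)]`. Confidence (the max component) never increases.
#'
#' @param b Probability 2-vector.
#' @param kernel A [volatility_kernel] (or switch-probability scalar).
#' @return Probability 2-vector.
#' @export
decay_belief <- function(b, kernel) {
  check_prob(b, 2, tol = 1e-6)
  v <- as.numeric(kernel)
  c(b[1] * (1 - v) + b[2] * v, b[1] * v + b[2] * (1 - v))
}

#' Project core belief to the lower (within-meeting) level
#'
#' Lower-level beliefs about claims are initialized from the higher-level
#' (cross-meeting) core belief; the mapping is the identity.
#'
#' @param core Probability 2-vector.
#' @return Probability 2-vector.
#' @export
project_to_lower <- function(core) {
  stopifnot(length(core) == 2)
  clamp_prob(core)
}

#' Infer the interlocutor's idea state from their observed expression
#'
#' Within a meeting the posterior over the partner's idea state is set to the
#' (clamped) observed expression distribution: expressed support is taken at
#' face value as evidence about the speaker's belief.
#'
#' @param observed_expr Probability 2-vector (the partner's expressed support).
#' @return Probability 2-vector.
#' @export
infer_interlocutor_belief <- function(observed_expr) {
  stopifnot(length(observed_expr) == 2)
  clamp_prob(observed_expr)
}

#' Update the core belief from self- and other-expressions
#'
#' Bayesian belief update in log space:
#' `posterior = softmax(ln prior + gamma_self ln o_self + gamma_other ln o_other)`.
#' The likelihood precisions weigh how much evidence each expression carries;
#' with both precisions zero the posterior equals the prior. This is the
#' explicit coupling between interlocutors: higher sensitivity to the
#' partner's claims induces more belief updating.
#'
#' @param prior Core belief (probability 2-vector).
#' @param o_self The agent's own emitted expression for this meeting.
#' @param o_other The partner's observed expression.
#' @param gamma_self,gamma_other Non-negative likelihood precisions.
#' @return Posterior core belief (probability 2-vector).
#' @export
#' @examples
#' update_core_belief(c(0.9, 0.1), c(0.9, 0.1), c(0.2, 0.8), 0, 1)
update_core_belief <- function(prior, o_self, o_other,
                               gamma_self, gamma_other) {
  if (gamma_self < 0 || gamma_other < 0) stop("precisions must be >= 0")
  logit <- log(clamp_prob(prior)) +
    gamma_self * log(clamp_prob(o_self)) +
    gamma_other * log(clamp_prob(o_other))
  softmax(logit)
}
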