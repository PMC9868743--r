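# Meeting selection by expected free energy.
#
# Each day an agent scores every candidate partner (including itself = stay
# home) with an expected free energy G combining a pragmatic term -- the
# divergence of the candidate's expected expression from the agent's
# confirmation-biased preferences -- and an epistemic term rewarding
# candidates whose current beliefs are ambiguous (not recently visited). The
# visit policy is a precision-weighted softmax over -G plus a habitual
# visitation prior.

# Epistemic bonus available from a candidate not seen within the memory
# window (ambiguity left to reduce).
AMBIGUITY_BONUS <- 0.1

#' Project a belief about a candidate through the travel transition
#'
#' Expected idea-belief about a candidate after the between-meeting
#' transition; identical in form to [decay_belief()].
#'
#' @param x_home Current belief about the candidate's idea state.
#' @param kernel A [volatility_kernel].
#' @return Probability 2-vector.
#' @export
travel_projection <- function(x_home, kernel) {
  decay_belief(x_home, kernel)
}

#' Expected expression from a candidate
#'
#' Marginalizes the projected belief about the candidate through the
#' expression likelihood map: what support would this candidate be expected
#' to voice?
#'
#' @param x_visit Projected belief about the candidate (probability 2-vector).
#' @param a_idea 2x2 row-stochastic expression likelihood.
#' @return Probability 2-vector over expressed support.
#' @export
expected_expression <- function(x_visit, a_idea) {
  apply_map(a_idea, x_visit)
}

#' Log-preferences over expressed support from the core belief
#'
#' `C = ln(t(a_c) %*% x_core)` (clamped before the log). With a near-identity
#' `a_c` (strong confirmation bias) preferences mirror the core belief
#' one-to-one; with near-uniform rows preferences are belief-independent.
#'
#' @param core Core belief (probability 2-vector).
#' @param a_c 2x2 row-stochastic confirmation-bias map.
#' @return Numeric 2-vector of log-preferences.
#' @export
preference_from_core <- function(core, a_c) {
  log(clamp_prob(apply_map(a_c, clamp_prob(core))))
}

#' Epistemic ambiguity of a candidate
#'
#' 0 if the candidate was visited within the last `window` days (no ambiguity
#' left to reduce), 0.1 otherwise (including never seen).
#'
#' @param last_seen Day index of the most recent conversation with the
#'   candidate, or `NA` if never.
#' @param today Current day index.
#' @param window Memory length in days (default 5).
#' @return 0 or 0.1.
#' @export
ambiguity_term <- function(last_seen, today, window = 5) {
  if (window < 0) stop("window must be >= 0")
  if (is.na(last_seen)) return(AMBIGUITY_BONUS)
  if (last_seen > today) stop("last_seen is in the future")
  if (today - last_seen <= window) 0 else AMBIGUITY_BONUS
}

#' Expected free energy of visiting one candidate
#'
#' The pragmatic (risk) term is `o . (ln o - C)`, the divergence of the
#' candidate's expected expression from the agent's preferences; the epistemic
#' term carries the ambiguity `h` of the candidate. By default ambiguity is a
#' bonus (epistemic value: `G = pragmatic - h`), so that minimizing G attracts
#' agents to candidates whose beliefs are unknown (novelty seeking).
#' `novelty_bonus = FALSE` uses the additive penalty convention
#' (`G = pragmatic + h`) instead.
#'
#' @param o_expected Expected expression of the candidate (probability
#'   2-vector).
#' @param c_idea Log-preference 2-vector (from [preference_from_core()]).
#' @param h Ambiguity scalar (from [ambiguity_term()]).
#' @param novelty_bonus If `TRUE` (default), ambiguity reduces G.
#' @return List with `pragmatic`, `epistemic` and `total` scalars
#'   (`total = pragmatic + epistemic`).
#' @export
expected_free_energy <- function(o_expected, c_idea, h, novelty_bonus = TRUE) {
  check_prob(o_expected, 2, tol = 1e-6)
  if (length(c_idea) != 2 || !all(is.finite(c_idea)) || !is.finite(h)) {
    stop("invalid preference vector or ambiguity")
  }
  o <- clamp_prob(o_expected)
  pragmatic <- sum(o * (log(o) - c_idea))
  epistemic <- if (novelty_bonus) -h else h
  list(pragmatic = pragmatic, epistemic = epistemic,
       total = pragmatic + epistemic)
}

#' Visit policy over all candidates
#'
#' `u_visit = softmax(-gamma_g * G + gamma_e * E_visit)`, where `E_visit` is
#' the normalized visitation-habit prior (a probability vector entering the
#' softmax directly, so habit contributes a bounded bias). Lower expected
#' free energy means higher visit probability; the policy is invariant to
#' adding a constant to all G entries.
#'
#' @param g Numeric vector of per-candidate expected free energies.
#' @param habit Visitation-habit prior (probability vector, same length).
#' @param gamma_g Non-negative EFE precision.
#' @param gamma_e Non-negative habit precision.
#' @return Probability vector over candidates (self-index = stay home).
#' @export
visit_policy <- function(g, habit, gamma_g, gamma_e) {
  if (!all(is.finite(g)) || gamma_g < 0 || gamma_e < 0) {
    stop("invalid expected free energies or precisions")
  }
  if (length(g) != length(habit)) {
    stop("expected free energy and habit prior lengths differ")
  }
  habit <- habit / sum(habit)
  softmax(-gamma_g * g + gamma_e * habit)
}

#' Select an interlocutor from a visit policy
#'
#' Categorical draw from the policy; drawing one's own index means staying
#' home. In deterministic mode the argmax is taken, ties broken by the lowest
#' index.
#'
#' @param policy Probability vector over candidates.
#' @param deterministic If `TRUE`, take the argmax instead of sampling.
#' @return Integer candidate index.
#' @export
select_interlocutor <- function(policy, deterministic = FALSE) {
  check_prob(policy, tol = 1e-6)
  if (deterministic) return(which.max(policy))
  sample.int(length(policy), 1, prob = policy)
}
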