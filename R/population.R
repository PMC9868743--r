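# Population generation and simulation scheduling.
#
# A community of agents with identical model structure but individualized
# parameters: likelihood precisions drawn from a right-skewed gamma
# distribution (most agents quite sensitive to others' claims), per-agent
# volatility kernels from a gamma-distributed transition precision, a
# confirmation-bias subgroup split (near-identity vs. mild preference maps),
# a spread of initial status-quo support, and a single "rogue" dissenter who
# strongly supports the alternative idea and is fully insensitive to others'
# claims. Each simulated day every agent (1) decays beliefs, (2) selects one
# interlocutor by expected free energy, and (3) holds one conversation per
# visit: both parties emit an expression plus affective cue, update core
# beliefs, accumulate valence-likelihood and habit counts, and record the
# visit.

#' Configuration for a population simulation
#'
#' All tunable parameters of the community simulation with their defaults.
#' Parameters not fixed by the underlying model description are documented in
#' the methods vignette.
#'
#' @param n_agents Number of agents (>= 2). Default 50.
#' @param n_days Number of simulated days. Default 100.
#' @param high_bias_fraction Fraction of agents given the strong
#'   confirmation-bias preference map (nearest rounding, half up). Default 0.5.
#' @param master_seed Integer master seed; all randomness derives from it.
#' @param gamma_a_shape,gamma_a_scale Gamma distribution of the likelihood
#'   precision gamma_A (sensitivity to others' claims). Defaults 4 and 0.75
#'   (mean 3, right-skewed toward high sensitivity).
#' @param gamma_self Fixed self-evidence precision in the core-belief update.
#'   Default 0.5.
#' @param gamma_b_shape,gamma_b_scale Gamma distribution of the transition
#'   precision controlling belief volatility. Defaults 3 and 2.
#' @param strong_bias_blend,weak_bias_blend Identity-vs-uniform blend of the
#'   confirmation-bias map for the two subgroups. Defaults 0.95 and 0.6.
#' @param a_idea_blend Blend of the expression likelihood map used to form
#'   expectations about candidates. Default 0.9.
#' @param memory_window Visit-memory length in days. Default 5.
#' @param gamma_g_visit Scale multiplier on the valence-conditioned expected
#'   free energy precision (the per-day precision is drawn from
#'   `Gamma(1, beta_expr)` like the expression precision). Default 1.
#' @param gamma_e_visit Precision on the visitation habit. Default 0.5.
#' @param gamma_e_expr Precision on the expression habit. Default 1.
#' @param gamma_a2 Valence-likelihood learning precision. Default 0.5.
#' @param habit_increment Count added per action taken. Default 1.
#' @param support_range Range of initial status-quo support for the n-1
#'   consensus agents. Default c(0.6, 0.98).
#' @param rogue_support Initial status-quo support of the rogue agent.
#'   Default 0.02.
#' @param consensus_prior Initial belief every agent holds about every other
#'   agent's idea state. Default c(0.8, 0.2).
#' @param include_rogue Include the rogue dissenter (last index). Default TRUE.
#' @param novelty_bonus Ambiguity enters expected free energy as a bonus
#'   (novelty seeking). Default TRUE.
#' @param printed_sign Use the flipped belief-term sign in the expression
#'   policy. Default FALSE.
#' @param deterministic Replace stochastic draws (expression precision,
#'   emissions, partner choice) by their means/argmax. Default FALSE.
#' @return An object of class `population_config` (a named list).
#' @export
population_config <- function(n_agents = 50,
                              n_days = 100,
                              high_bias_fraction = 0.5,
                              master_seed = 1,
                              gamma_a_shape = 4,
                              gamma_a_scale = 0.75,
                              gamma_self = 0.5,
                              gamma_b_shape = 3,
                              gamma_b_scale = 2,
                              strong_bias_blend = 0.95,
                              weak_bias_blend = 0.6,
                              a_idea_blend = 0.9,
                              memory_window = 5,
                              gamma_g_visit = 1,
                              gamma_e_visit = 0.5,
                              gamma_e_expr = 1,
                              gamma_a2 = 0.5,
                              habit_increment = 1,
                              support_range = c(0.6, 0.98),
                              rogue_support = 0.02,
                              consensus_prior = c(0.8, 0.2),
                              include_rogue = TRUE,
                              novelty_bonus = TRUE,
                              printed_sign = FALSE,
                              deterministic = FALSE) {
  stopifnot(n_agents >= 2, n_days >= 0,
            high_bias_fraction >= 0, high_bias_fraction <= 1,
            master_seed == floor(master_seed))
  cfg <- as.list(environment())
  structure(cfg, class = "population_config")
}

# Derive a bounded positive integer seed from the master seed and an offset.
derive_seed <- function(master_seed, offset) {
  as.integer((abs(master_seed) + offset) %% (2^31 - 1)) + 1L
}

#' Generate the heterogeneous agent population
#'
#' Draws every agent's individual parameters and initial state from the
#' configured hyperparameter distributions. `round(high_bias_fraction * n)`
#' agents (half rounded up) receive the strong confirmation-bias map; all but
#' one agent start supporting the status quo with per-agent strength drawn
#' uniformly from `support_range`; the last agent is the rogue: it strongly
#' supports the alternative idea, has zero sensitivity to others' claims, and
#' a mirrored valence prior. Fully reproducible for a given seed.
#'
#' @param config A [population_config].
#' @return List of agent bundles; each bundle has `params` (precisions, maps,
#'   kernel, bias group, rogue flag) and `state` (core belief, alpha counts,
#'   habit counts, beliefs about others, visit memory).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_agents

  # population-level assignments
  set.seed(derive_seed(config$master_seed, 0))
  k_strong <- floor(config$high_bias_fraction * n + 0.5)
  strong_idx <- if (k_strong > 0) sample.int(n, k_strong) else integer(0)
  rogue_idx <- if (config$include_rogue) n else 0L

  agents <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$master_seed, 7919 * i))
    gamma_a <- stats::rgamma(1, shape = config$gamma_a_shape,
                             scale = config$gamma_a_scale)
    gamma_b <- stats::rgamma(1, shape = config$gamma_b_shape,
                             scale = config$gamma_b_scale)
    d_support <- stats::runif(1, config$support_range[1],
                              config$support_range[2])

    is_rogue <- i == rogue_idx
    bias_group <- if (i %in% strong_idx) "strong" else "weak"
    blend <- if (bias_group == "strong") config$strong_bias_blend else
      config$weak_bias_blend

    d <- if (is_rogue) c(config$rogue_support, 1 - config$rogue_support) else
      c(d_support, 1 - d_support)

    # valence-likelihood prior: the phenotype-congruent idea row is strongly
    # mapped (4:1) to positive valence; the other idea's row is near-flat
    # with small total mass (minimal precision for the unfamiliar belief).
    alpha <- if (is_rogue) {
      rbind(c(0.5, 0.5), c(4, 1))
    } else {
      rbind(c(4, 1), c(0.5, 0.5))
    }

    params <- list(
      # the rogue is fully resistant: neither others' claims nor its own
      # expression noise move its core belief (only decay does)
      gamma_a_other = if (is_rogue) 0 else gamma_a,
      gamma_a_self = if (is_rogue) 0 else config$gamma_self,
      kernel = kernel_from_precision(gamma_b),
      a_c = blend_identity(blend),
      a_idea = blend_identity(config$a_idea_blend),
      bias_group = bias_group,
      is_rogue = is_rogue
    )

    x_others <- matrix(rep(clamp_prob(config$consensus_prior), each = n),
                       nrow = n)

    state <- list(
      core = init_core_belief(d),
      alpha = alpha,
      eps_expr = c(1, 1),
      eps_visit = rep(1, n),
      x_others = x_others,
      last_seen = rep(NA_real_, n)
    )
    agents[[i]] <- list(id = i, params = params, state = state)
  }
  agents
}

# One agent's utterance for the current conversation: valence from the
# learned likelihood, expression precision from valence, policy from belief
# plus habit, noisy emission.
make_utterance <- function(agent, config) {
  a_sat <- counts_to_likelihood(agent$state$alpha)
  x_sat <- infer_valence(agent$state$core, a_sat)
  beta <- expression_rate(x_sat)
  g_expr <- sample_expression_precision(beta,
                                        deterministic = config$deterministic)
  u <- expression_policy(agent$state$core,
                         habit_to_prior(agent$state$eps_expr),
                         g_expr, config$gamma_e_expr,
                         printed_sign = config$printed_sign)
  out <- emit_expression(u, x_sat, deterministic = config$deterministic)
  out$x_sat <- x_sat
  out
}

# Visit policy of agent i over all candidates, from start-of-day state.
# The EFE precision is valence-conditioned like the expression precision:
# positive valence gives confident (deliberate) partner choice, negative or
# uncertain valence leaves choice closer to habit and chance.
agent_visit_policy <- function(agent, day, config) {
  n <- config$n_agents
  i <- agent$id
  xb <- agent$state$x_others
  xb[i, ] <- agent$state$core
  v <- as.numeric(agent$params$kernel)

  # travel projection of candidate beliefs, then expected expressions
  x_proj <- cbind(xb[, 1] * (1 - v) + xb[, 2] * v,
                  xb[, 1] * v + xb[, 2] * (1 - v))
  o <- x_proj %*% agent$params$a_idea
  o <- pmin(pmax(o, PROB_EPS), 1 - PROB_EPS)
  o <- o / rowSums(o)

  c_idea <- preference_from_core(agent$state$core, agent$params$a_c)
  pragmatic <- rowSums(o * (log(o) - matrix(c_idea, n, 2, byrow = TRUE)))

  seen <- agent$state$last_seen
  h <- ifelse(is.na(seen) | day - seen > config$memory_window,
              AMBIGUITY_BONUS, 0)
  h[i] <- 0  # no ambiguity about one's own beliefs

  epi <- if (config$novelty_bonus) -h else h
  g <- pragmatic + epi

  x_sat <- infer_valence(agent$state$core,
                         counts_to_likelihood(agent$state$alpha))
  gamma_g <- config$gamma_g_visit *
    sample_expression_precision(expression_rate(x_sat),
                                deterministic = config$deterministic)
  visit_policy(g, habit_to_prior(agent$state$eps_visit),
               gamma_g, config$gamma_e_visit)
}

# One conversation between visitor and host: both emit, both update beliefs,
# counts and memory. Returns the updated agents plus a meeting record.
hold_conversation <- function(visitor, host, day, config) {
  utt_v <- make_utterance(visitor, config)
  utt_h <- make_utterance(host, config)

  new_core <- function(agent, own, other) {
    update_core_belief(agent$state$core, own$o_expr, other$o_expr,
                       agent$params$gamma_a_self, agent$params$gamma_a_other)
  }
  core_v <- new_core(visitor, utt_v, utt_h)
  core_h <- new_core(host, utt_h, utt_v)

  update_party <- function(agent, core, partner_id, own, other) {
    agent$state$core <- core
    agent$state$x_others[partner_id, ] <- infer_interlocutor_belief(other$o_expr)
    agent$state$alpha <- update_valence_likelihood(
      agent$state$alpha, other$o_expr, other$o_affect, config$gamma_a2)
    agent$state$eps_expr <- update_habit(
      agent$state$eps_expr, which.max(own$o_expr), config$habit_increment)
    agent$state$last_seen <- record_visit(agent$state$last_seen, partner_id,
                                          day)
    agent
  }
  visitor <- update_party(visitor, core_v, host$id, utt_v, utt_h)
  host <- update_party(host, core_h, visitor$id, utt_h, utt_v)

  record <- c(day = day, visitor = visitor$id, host = host$id,
              visitor_support_expressed = utt_v$o_expr[1],
              host_support_expressed = utt_h$o_expr[1],
              visitor_affect_pos = utt_v$o_affect[1],
              host_affect_pos = utt_h$o_affect[1],
              visitor_support_after = core_v[1],
              host_support_after = core_h[1])
  list(visitor = visitor, host = host, record = record)
}

meeting_record_names <- c(
  "day", "visitor", "host", "visitor_support_expressed",
  "host_support_expressed", "visitor_affect_pos", "host_affect_pos",
  "visitor_support_after", "host_support_after")

empty_meetings <- function() {
  df <- as.data.frame(matrix(numeric(0), 0, length(meeting_record_names)))
  names(df) <- meeting_record_names
  df
}

#' Run one simulated day
#'
#' In order: (1) every agent's core belief and beliefs about others decay
#' under its volatility kernel; (2) every agent computes its visit policy
#' from start-of-day states and selects a partner (simultaneous selection);
#' (3) visitor-host conversations are resolved in random order, one
#' conversation per visitor (hosts may receive several visitors); stay-home
#' agents hold no conversation. Visitation habits are reinforced for the
#' selection taken, including staying home.
#'
#' @param agents List of agent bundles (from [generate_population()]).
#' @param day Day index (1-based).
#' @param config The [population_config].
#' @return List with `agents` (updated) and `meetings` (data frame of
#'   conversation records, zero rows if none).
#' @export
run_day <- function(agents, day, config) {
  n <- length(agents)

  for (i in seq_len(n)) {
    st <- agents[[i]]$state
    kern <- agents[[i]]$params$kernel
    st$core <- decay_belief(st$core, kern)
    v <- as.numeric(kern)
    st$x_others <- cbind(st$x_others[, 1] * (1 - v) + st$x_others[, 2] * v,
                         st$x_others[, 1] * v + st$x_others[, 2] * (1 - v))
    agents[[i]]$state <- st
  }

  choices <- integer(n)
  for (i in seq_len(n)) {
    pol <- agent_visit_policy(agents[[i]], day, config)
    choices[i] <- select_interlocutor(pol,
                                      deterministic = config$deterministic)
    agents[[i]]$state$eps_visit <- update_habit(
      agents[[i]]$state$eps_visit, choices[i], config$habit_increment)
  }

  visitors <- which(choices != seq_len(n))
  if (length(visitors) > 1 && !config$deterministic) {
    visitors <- visitors[sample.int(length(visitors))]
  }

  records <- vector("list", length(visitors))
  for (k in seq_along(visitors)) {
    i <- visitors[k]
    j <- choices[i]
    out <- hold_conversation(agents[[i]], agents[[j]], day, config)
    agents[[i]] <- out$visitor
    agents[[j]] <- out$host
    records[[k]] <- out$record
  }

  meetings <- if (length(records)) {
    df <- as.data.frame(do.call(rbind, records))
    names(df) <- meeting_record_names
    df
  } else {
    empty_meetings()
  }
  list(agents = agents, meetings = meetings)
}

#' Run a full population simulation
#'
#' Generates the population and simulates `n_days` days. Deterministic for a
#' given configuration and master seed.
#'
#' @param config A [population_config].
#' @return An object of class `population_trajectory`: list with `support`
#'   (`(n_days + 1) x n_agents` matrix of status-quo support, day 0 = initial
#'   state), `valence` (same shape, positive-valence probability),
#'   `final_beliefs` (`n_agents x 2`), `meetings` (data frame), and `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "population_config"))
  agents <- generate_population(config)
  set.seed(derive_seed(config$master_seed, 104729))

  n <- config$n_agents
  support <- matrix(NA_real_, config$n_days + 1, n)
  valence <- matrix(NA_real_, config$n_days + 1, n)

  snapshot <- function(agents, row) {
    for (i in seq_len(n)) {
      st <- agents[[i]]$state
      support[row, i] <<- st$core[1]
      valence[row, i] <<- infer_valence(st$core,
                                        counts_to_likelihood(st$alpha))[1]
    }
  }
  snapshot(agents, 1)

  meeting_log <- vector("list", config$n_days)
  for (day in seq_len(config$n_days)) {
    out <- run_day(agents, day, config)
    agents <- out$agents
    meeting_log[[day]] <- out$meetings
    snapshot(agents, day + 1)
  }

  meetings <- if (config$n_days > 0) do.call(rbind, meeting_log) else
    empty_meetings()
  final_beliefs <- t(vapply(agents, function(a) a$state$core, numeric(2)))

  structure(list(support = support, valence = valence,
                 final_beliefs = final_beliefs, meetings = meetings,
                 agents = agents, config = config),
            class = "population_trajectory")
}

#' Simulate a dyadic dialogue
#'
#' Two agents starting from opposing beliefs alternate expressing their
#' current belief and updating from the partner's expression; agent 1 speaks
#' on odd exchanges, agent 2 on even ones. With high symmetric likelihood
#' precision the beliefs converge onto one shared belief (generalized
#' synchrony); with low precision each agent sticks to its own belief. In the
#' default deterministic mode the expression equals the speaker's current
#' belief; otherwise it is a Dirichlet draw around it.
#'
#' @param gamma1,gamma2 Likelihood precisions (sensitivity to the partner's
#'   claims) of agents 1 and 2.
#' @param n_steps Number of exchanges (default 18).
#' @param init1,init2 Initial beliefs. Defaults c(0.9, 0.1) and c(0.1, 0.9).
#' @param gamma_self Self-evidence precision (default 0: pure listening).
#' @param switch_prob Per-exchange belief volatility (default 0).
#' @param deterministic If `TRUE` (default), expressions equal beliefs.
#' @param seed Optional seed for the stochastic mode.
#' @return Object of class `dyad_trajectory`: list with `belief1`, `belief2`
#'   (`(n_steps + 1) x 2` matrices, row 1 = initial state), `support1`,
#'   `support2` (status-quo support series) and `gap` (absolute support
#'   difference per step).
#' @export
simulate_dyad <- function(gamma1, gamma2, n_steps = 18,
                          init1 = c(0.9, 0.1), init2 = c(0.1, 0.9),
                          gamma_self = 0, switch_prob = 0,
                          deterministic = TRUE, seed = NULL) {
  stopifnot(n_steps >= 1, gamma1 >= 0, gamma2 >= 0)
  if (!is.null(seed)) set.seed(derive_seed(seed, 0))
  kern <- volatility_kernel(switch_prob)

  x <- list(init_core_belief(init1), init_core_belief(init2))
  gam <- c(gamma1, gamma2)
  b1 <- matrix(NA_real_, n_steps + 1, 2)
  b2 <- matrix(NA_real_, n_steps + 1, 2)
  b1[1, ] <- x[[1]]; b2[1, ] <- x[[2]]

  for (t in seq_len(n_steps)) {
    speaker <- if (t %% 2 == 1) 1 else 2
    listener <- 3 - speaker
    x[[1]] <- decay_belief(x[[1]], kern)
    x[[2]] <- decay_belief(x[[2]], kern)
    o <- if (deterministic) x[[speaker]] else
      dirichlet_sample(EXPR_CONCENTRATION * x[[speaker]])
    x[[listener]] <- update_core_belief(x[[listener]], x[[listener]], o,
                                        gamma_self, gam[listener])
    b1[t + 1, ] <- x[[1]]
    b2[t + 1, ] <- x[[2]]
  }

  structure(list(belief1 = b1, belief2 = b2,
                 support1 = b1[, 1], support2 = b2[, 1],
                 gap = abs(b1[, 1] - b2[, 1])),
            class = "dyad_trajectory")
}
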