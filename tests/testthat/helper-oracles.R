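# Independent oracles used to freeze expected values.

# Brute-force KL divergence: plain element-wise sum, no shared code with
# kl_divergence().
kl_oracle <- function(p, q) {
  total <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) total <- total + p[i] * log(p[i] / q[i])
  }
  total
}

# Plain softmax oracle.
softmax_oracle <- function(logits, gamma = 1) {
  e <- exp(gamma * logits)
  e / sum(e)
}

# Two-agent alternating-exchange recursion, written out directly: agent 1
# speaks on odd exchanges, the listener multiplies its belief by the speaker's
# belief raised to its own coupling precision and renormalizes. No decay, no
# noise, no self term.
dyad_oracle <- function(gamma1, gamma2, n_steps,
                        init1 = c(0.9, 0.1), init2 = c(0.1, 0.9)) {
  eps <- 1e-6
  squash <- function(p) {
    p <- p / sum(p)
    p <- pmin(pmax(p, eps), 1 - eps)
    p / sum(p)
  }
  x1 <- squash(init1); x2 <- squash(init2)
  s1 <- numeric(n_steps + 1); s2 <- numeric(n_steps + 1)
  s1[1] <- x1[1]; s2[1] <- x2[1]
  for (t in seq_len(n_steps)) {
    if (t %% 2 == 1) {
      x2 <- squash(x2 * squash(x1)^gamma2)
    } else {
      x1 <- squash(x1 * squash(x2)^gamma1)
    }
    s1[t + 1] <- x1[1]; s2[t + 1] <- x2[1]
  }
  list(support1 = s1, support2 = s2, gap = abs(s1 - s2))
}

# Small population configuration for fast invariant-style runs; any field
# can be overridden.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_agents = 12, n_days = 15, master_seed = 42), list(...))
  do.call(population_config, args)
}
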