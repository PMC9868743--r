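test_that("population generation matches the configured composition", {
  cfg <- population_config(master_seed = 5)
  agents <- generate_population(cfg)
  expect_length(agents, 50)

  support0 <- sapply(agents, function(a) a$state$core[1])
  expect_equal(sum(support0 > 0.5), 49)
  rogue <- agents[[50]]
  expect_true(rogue$params$is_rogue)
  expect_lt(rogue$state$core[1], 0.1)
  expect_equal(rogue$params$gamma_a_other, 0)

  n_strong <- sum(sapply(agents, function(a) a$params$bias_group == "strong"))
  expect_equal(n_strong, 25)

  # half-up rounding of the strong-bias subgroup size
  cfg15 <- population_config(high_bias_fraction = 0.15, master_seed = 5)
  n15 <- sum(sapply(generate_population(cfg15),
                    function(a) a$params$bias_group == "strong"))
  expect_equal(n15, 8)
  cfg85 <- population_config(high_bias_fraction = 0.85, master_seed = 5)
  n85 <- sum(sapply(generate_population(cfg85),
                    function(a) a$params$bias_group == "strong"))
  expect_equal(n85, 43)
})

test_that("population generation is deterministic per seed", {
  cfg <- population_config(master_seed = 77, n_agents = 10)
  a1 <- generate_population(cfg)
  a2 <- generate_population(cfg)
  expect_identical(a1, a2)
  a3 <- generate_population(population_config(master_seed = 78, n_agents = 10))
  expect_false(identical(a1, a3))
})

test_that("a conversation under high coupling pulls beliefs together", {
  cfg <- small_config(deterministic = TRUE)
  agents <- generate_population(cfg)
  a <- agents[[1]]; b <- agents[[2]]
  a$state$core <- c(0.9, 0.1); b$state$core <- c(0.2, 0.8)
  a$params$gamma_a_other <- 3; b$params$gamma_a_other <- 3
  gap_before <- abs(a$state$core[1] - b$state$core[1])
  out <- culturesim:::hold_conversation(a, b, day = 1, cfg)
  gap_after <- abs(out$visitor$state$core[1] - out$host$state$core[1])
  expect_lt(gap_after, gap_before)
  # both parties remember the meeting
  expect_equal(out$visitor$state$last_seen[b$id], 1)
  expect_equal(out$host$state$last_seen[a$id], 1)
})

test_that("run_day bookkeeping is consistent", {
  cfg <- small_config()
  agents <- generate_population(cfg)
  set.seed(123)
  out <- run_day(agents, 1, cfg)
  m <- out$meetings
  expect_true(all(m$visitor != m$host))
  expect_true(all(m$visitor_support_expressed > 0 &
                    m$visitor_support_expressed < 1))
  # every visitor appears once as a visitor
  expect_false(any(duplicated(m$visitor)))
})

test_that("simulation trajectories are valid, seeded, and sized correctly", {
  cfg <- small_config()
  traj <- run_simulation(cfg)
  expect_s3_class(traj, "population_trajectory")
  expect_equal(dim(traj$support), c(cfg$n_days + 1, cfg$n_agents))
  expect_true(all(traj$support >= 0 & traj$support <= 1))
  expect_true(all(traj$valence >= 0 & traj$valence <= 1))

  traj2 <- run_simulation(cfg)
  expect_identical(traj$support, traj2$support)
  expect_identical(traj$meetings, traj2$meetings)

  traj3 <- run_simulation(small_config(master_seed = 43))
  expect_false(identical(traj$support, traj3$support))

  # n_days = 0: initial state only
  traj0 <- run_simulation(small_config(n_days = 0))
  expect_equal(nrow(traj0$support), 1)
  expect_equal(nrow(traj0$meetings), 0)
})

test_that("the rogue's belief follows the pure decay recursion exactly", {
  cfg <- small_config(n_days = 25)
  agents <- generate_population(cfg)
  rogue_id <- cfg$n_agents
  v <- as.numeric(agents[[rogue_id]]$params$kernel)
  s <- agents[[rogue_id]]$state$core[1]
  expected <- numeric(cfg$n_days + 1)
  expected[1] <- s
  for (t in seq_len(cfg$n_days)) {
    s <- s * (1 - v) + (1 - s) * v
    expected[t + 1] <- s
  }
  traj <- run_simulation(cfg)
  expect_equal(traj$support[, rogue_id], expected, tolerance = 1e-9)
})

test_that("dyad simulation matches its documented limits", {
  flat <- simulate_dyad(0, 0, n_steps = 10)
  expect_equal(flat$support1, rep(flat$support1[1], 11))
  expect_equal(flat$support2, rep(flat$support2[1], 11))

  conv <- simulate_dyad(3, 3, n_steps = 18)
  expect_lt(conv$gap[19], 0.05)

  # stochastic mode is seed-reproducible
  s1 <- simulate_dyad(2, 2, n_steps = 12, deterministic = FALSE, seed = 4)
  s2 <- simulate_dyad(2, 2, n_steps = 12, deterministic = FALSE, seed = 4)
  expect_identical(s1$support1, s2$support1)
})
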