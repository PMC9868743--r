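test_that("population-average support summarizes the trajectory", {
  m <- rbind(c(1, 1), c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(population_average_support(m), c(1, 0.5, 0.5))
  expect_error(population_average_support(matrix(numeric(0), 0, 2)), "empty")
})

test_that("segregation index counts groups and the mid-band", {
  ext <- c(rep(0.9, 25), rep(0.1, 25))
  seg <- segregation_index(ext)
  expect_equal(seg$n_status_quo, 25)
  expect_equal(seg$n_alternative, 25)
  expect_equal(seg$mid_band_fraction, 0)

  expect_equal(segregation_index(rep(0.5, 10))$mid_band_fraction, 1)
})

test_that("dyad convergence flags and first crossing are computed", {
  d <- dyad_convergence(c(0.5, 0.5), c(0.5, 0.5))
  expect_true(d$converged)
  expect_equal(d$final_gap, 0)
  expect_equal(d$first_crossing, 1)

  d2 <- dyad_convergence(rep(0.9, 5), rep(0.1, 5))
  expect_false(d2$converged)
  expect_equal(d2$final_gap, 0.8)
  expect_true(is.na(d2$first_crossing))

  expect_error(dyad_convergence(1:3 / 10, 1:4 / 10), "lengths differ")

  # gap shrinks monotonically under high symmetric coupling
  traj <- simulate_dyad(3, 3, n_steps = 18)
  expect_true(all(diff(traj$gap) <= 1e-9))
  expect_true(dyad_convergence(traj)$converged)
})

test_that("outputs round-trip losslessly through CSV and JSON", {
  cfg <- small_config(n_days = 6)
  traj <- run_simulation(cfg)
  out <- withr::local_tempdir()
  paths <- write_outputs(traj, out)
  expect_true(all(file.exists(paths)))

  back <- read_trajectory_csv(paths["trajectory"])
  expect_equal(back$support, traj$support, tolerance = 0)
  expect_equal(back$valence, traj$valence, tolerance = 0)
  expect_equal(nrow(utils::read.csv(paths["trajectory"])),
               (cfg$n_days + 1) * cfg$n_agents)

  js <- jsonlite::read_json(paths["summary"], simplifyVector = TRUE)
  expect_equal(js$master_seed, cfg$master_seed)
  expect_equal(js$final_mean_support, mean(traj$final_beliefs[, 1]),
               tolerance = 1e-12)

  # summary metrics recomputed from the serialized trajectory match
  final_row <- back$support[nrow(back$support), ]
  expect_equal(mean(final_row), js$final_mean_support, tolerance = 1e-12)
  seg <- segregation_index(final_row)
  expect_equal(seg$mid_band_fraction, js$segregation$mid_band_fraction)
})

test_that("config files round-trip through YAML and JSON", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_agents: 8", "n_days: 3", "high_bias_fraction: 0.25",
               "master_seed: 9"), yml)
  cfg <- read_config(yml)
  expect_s3_class(cfg, "population_config")
  expect_equal(cfg$n_agents, 8)
  expect_equal(cfg$high_bias_fraction, 0.25)
  expect_equal(cfg$memory_window, 5)  # default preserved

  jsn <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n_agents = 8, master_seed = 9), jsn,
                       auto_unbox = TRUE)
  expect_equal(read_config(jsn)$n_agents, 8)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("no_such_field: 1", bad)
  expect_error(read_config(bad), "unknown config fields")
})

test_that("bias-fraction sweeps use matched seeds per fraction", {
  res <- sweep_bias_fractions(c(0.2, 0.8), replicates = 2, seed = 3,
                              config = small_config(n_days = 4))
  expect_equal(nrow(res), 4)
  expect_equal(sort(unique(res$seed)), c(3, 4))
  expect_true(all(res$final_mean_support >= 0 & res$final_mean_support <= 1))
  expect_true(all(res$n_status_quo + res$n_alternative == 12))
})
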