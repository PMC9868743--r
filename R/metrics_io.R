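# Summary metrics, serialization and configuration plumbing.

#' Per-day population-average status-quo support
#'
#' @param trajectory A `population_trajectory` (or a day x agent support
#'   matrix).
#' @return Numeric vector, one mean per day (including day 0).
#' @export
population_average_support <- function(trajectory) {
  s <- if (inherits(trajectory, "population_trajectory")) trajectory$support
  else trajectory
  if (is.null(dim(s)) || nrow(s) == 0 || ncol(s) == 0) {
    stop("empty trajectory")
  }
  rowMeans(s)
}

#' Segregation summary of a final belief distribution
#'
#' Counts agents supporting the status quo (support > 0.5) vs. the alternative
#' (<= 0.5), and the fraction sitting in the undecided mid-band
#' `[0.4, 0.6]`. A segregated (bimodal) population has a small mid-band
#' fraction.
#'
#' @param final_beliefs `n x 2` belief matrix, or a vector of status-quo
#'   support values.
#' @return List with `n_status_quo`, `n_alternative`, `mid_band_fraction`.
#' @export
segregation_index <- function(final_beliefs) {
  support <- if (is.matrix(final_beliefs)) final_beliefs[, 1] else
    final_beliefs
  stopifnot(length(support) > 0, all(support >= 0), all(support <= 1))
  list(n_status_quo = sum(support > 0.5),
       n_alternative = sum(support <= 0.5),
       mid_band_fraction = mean(support >= 0.4 & support <= 0.6))
}

#' Convergence diagnostics for a dyadic dialogue
#'
#' @param series1,series2 Equal-length support series (or a `dyad_trajectory`
#'   as the first argument).
#' @param tol Convergence tolerance on the absolute gap (default 0.05).
#' @return List with `converged` (final gap < tol), `final_gap`, and
#'   `first_crossing` (first index with gap < tol, or `NA`).
#' @export
dyad_convergence <- function(series1, series2 = NULL, tol = 0.05) {
  if (inherits(series1, "dyad_trajectory")) {
    series2 <- series1$support2
    series1 <- series1$support1
  }
  if (length(series1) != length(series2)) {
    stop("series lengths differ")
  }
  gap <- abs(series1 - series2)
  final_gap <- gap[length(gap)]
  below <- which(gap < tol)
  list(converged = final_gap < tol,
       final_gap = final_gap,
       first_crossing = if (length(below)) below[1] else NA_integer_)
}

#' Summarize a population run
#'
#' @param trajectory A `population_trajectory`.
#' @return List with per-day average support, final-day segregation summary,
#'   group sizes, and the configuration echo (including the master seed).
#' @export
summarize_run <- function(trajectory) {
  stopifnot(inherits(trajectory, "population_trajectory"))
  seg <- segregation_index(trajectory$final_beliefs)
  list(average_support = population_average_support(trajectory),
       final_mean_support = mean(trajectory$final_beliefs[, 1]),
       segregation = seg,
       n_meetings = nrow(trajectory$meetings),
       config = unclass(trajectory$config))
}

#' Write simulation outputs to disk
#'
#' Writes the trajectory as CSV (`day`, `agent_id`, `support`, `valence_pos`;
#' day 0 is the initial state), the meeting log as CSV, and the run summary
#' plus full configuration and seed as JSON. The round trip through
#' [read_trajectory_csv()] reproduces the values to full float precision.
#'
#' @param trajectory A `population_trajectory`.
#' @param out_dir Output directory (created if missing).
#' @param prefix File-name prefix (default "run").
#' @return Invisibly, the named vector of file paths written.
#' @export
write_outputs <- function(trajectory, out_dir, prefix = "run") {
  stopifnot(inherits(trajectory, "population_trajectory"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory")
  }
  n_days <- nrow(trajectory$support) - 1
  n <- ncol(trajectory$support)
  traj_df <- data.frame(
    day = rep(0:n_days, times = n),
    agent_id = rep(seq_len(n), each = n_days + 1),
    support = as.vector(trajectory$support),
    valence_pos = as.vector(trajectory$valence)
  )
  paths <- c(
    trajectory = file.path(out_dir, paste0(prefix, "_trajectory.csv")),
    meetings = file.path(out_dir, paste0(prefix, "_meetings.csv")),
    summary = file.path(out_dir, paste0(prefix, "_summary.json"))
  )
  write_csv_full <- function(df, path) {
    # serialize doubles at 17 significant digits so the round trip is
    # lossless to full float precision
    for (col in names(df)) {
      if (is.double(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_csv_full(traj_df, paths["trajectory"])
  write_csv_full(trajectory$meetings, paths["meetings"])
  summary <- summarize_run(trajectory)
  summary$master_seed <- trajectory$config$master_seed
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a trajectory CSV back into matrices
#'
#' @param path Path to a `*_trajectory.csv` written by [write_outputs()].
#' @return List with `support` and `valence` matrices (day x agent).
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  n <- max(df$agent_id)
  n_rows <- max(df$day) + 1
  list(support = matrix(df$support, n_rows, n),
       valence = matrix(df$valence_pos, n_rows, n))
}

#' Read a population configuration from a YAML or JSON file
#'
#' Unknown fields are rejected; missing fields take the [population_config()]
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `population_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(population_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(population_config, vals)
}

#' Sweep the confirmation-bias composition
#'
#' Runs replicate simulations at each strong-bias fraction and summarizes the
#' final state of each run. Replicate r at every fraction uses master seed
#' `seed + r - 1`, so fractions are compared on matched seeds.
#'
#' @param fractions Numeric vector of `high_bias_fraction` values.
#' @param replicates Number of seeds per fraction (default 10).
#' @param seed Base master seed (default 1).
#' @param config Template [population_config()]; its fraction and seed are
#'   overridden.
#' @return Data frame with one row per run: `fraction`, `seed`,
#'   `final_mean_support`, `mid_band_fraction`, `n_status_quo`,
#'   `n_alternative`.
#' @export
sweep_bias_fractions <- function(fractions, replicates = 10, seed = 1,
                                 config = population_config()) {
  stopifnot(length(fractions) >= 1, replicates >= 1)
  rows <- list()
  for (f in fractions) {
    for (r in seq_len(replicates)) {
      cfg <- config
      cfg$high_bias_fraction <- f
      cfg$master_seed <- seed + r - 1
      traj <- run_simulation(cfg)
      seg <- segregation_index(traj$final_beliefs)
      rows[[length(rows) + 1]] <- data.frame(
        fraction = f, seed = cfg$master_seed,
        final_mean_support = mean(traj$final_beliefs[, 1]),
        mid_band_fraction = seg$mid_band_fraction,
        n_status_quo = seg$n_status_quo,
        n_alternative = seg$n_alternative)
    }
  }
  do.call(rbind, rows)
}
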