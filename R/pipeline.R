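#' Run configuration
#'
#' Resolved parameter set for a simulate/analyze run. Every analysis output
#' echoes its configuration and seeds so results are reproducible from the
#' sidecar alone.
#'
#' @param g Gravitational acceleration for model predictions, m/s^2.
#' @param frame_rate Synthetic motion-capture sampling rate, Hz.
#' @param t_n Flight duration of the synthetic base jump, seconds.
#' @param grid_half_width,grid_step Condition-grid geometry (see
#'   [condition_grid()]).
#' @param models Model names to score and correlate.
#' @param n_boot Bootstrap resample count.
#' @param n_participants,n_jumpers Simulated study design.
#' @param deformation_sd,jitter_sd Synthetic trajectory / marker noise,
#'   metres.
#' @param seed Master seed; all child streams derive from it.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(g = 9.81, frame_rate = 120, t_n = 1,
                       grid_half_width = 4L, grid_step = 0.175,
                       models = MODEL_NAMES, n_boot = 10000L,
                       n_participants = 32L, n_jumpers = 5L,
                       deformation_sd = 0, jitter_sd = 0.002,
                       seed = 1L) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  cfg <- list(g = g, frame_rate = frame_rate, t_n = t_n,
              grid_half_width = as.integer(grid_half_width),
              grid_step = grid_step, models = models,
              n_boot = as.integer(n_boot),
              n_participants = as.integer(n_participants),
              n_jumpers = as.integer(n_jumpers),
              deformation_sd = deformation_sd, jitter_sd = jitter_sd,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path JSON (or YAML, if the yaml package is installed) file whose
#'   fields override the defaults.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the `yaml` package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

# deterministic child seeds below 2^31, derived from the master seed
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 7919 + index * 104729) %% 2147483647)
}

#' Simulate a full synthetic rating study
#'
#' Generates the synthetic study described by a [run_config()]: one base
#' jump and point-light marker table per jumper, a rating table covering
#' every participant and condition, and a JSON sidecar echoing the resolved
#' configuration, child seeds and package version.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param observer An [observer_model()] describing the rating process.
#' @return Invisibly, a named list of written file paths.
#' @export
cmd_simulate <- function(config = run_config(), out_dir,
                         observer = observer_model(g = config$g)) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory `%s`", out_dir), call. = FALSE)
  }
  grid <- condition_grid(config$grid_half_width, config$grid_step)
  jumper_ids <- sprintf("J%02d", seq_len(config$n_jumpers))
  marker_paths <- character(0)
  base_traj <- NULL
  for (j in seq_along(jumper_ids)) {
    sj <- derive_seed(config$seed, j)
    traj <- synth_jump(t_n = config$t_n, g = config$g,
                       frame_rate = config$frame_rate,
                       deformation_sd = config$deformation_sd,
                       seed = sj, jumper_id = jumper_ids[j])
    if (j == 1L) base_traj <- traj
    tab <- synth_marker_table(traj, jitter_sd = config$jitter_sd,
                              seed = derive_seed(config$seed, 1000L + j))
    p <- file.path(out_dir, sprintf("markers_%s.csv", jumper_ids[j]))
    write_marker_csv(tab, p)
    marker_paths <- c(marker_paths, p)
  }
  traj_path <- file.path(out_dir, "base_trajectory.csv")
  write_trajectory_csv(base_traj, traj_path)

  ratings <- synth_ratings(base_traj, grid, observer,
                           n_participants = config$n_participants,
                           n_jumpers = config$n_jumpers,
                           seed = derive_seed(config$seed, 2000L))
  ratings_path <- file.path(out_dir, "ratings.csv")
  write_ratings_csv(ratings, ratings_path)

  sidecar <- list(
    package = "jumpnat",
    version = as.character(utils::packageVersion("jumpnat")),
    config = unclass(config),
    observer = unclass(observer),
    child_seeds = list(
      jumpers = vapply(seq_along(jumper_ids), function(j) derive_seed(config$seed, j), integer(1)),
      markers = vapply(seq_along(jumper_ids), function(j) derive_seed(config$seed, 1000L + j), integer(1)),
      ratings = derive_seed(config$seed, 2000L)
    ),
    files = list(markers = basename(marker_paths),
                 trajectory = basename(traj_path),
                 ratings = basename(ratings_path))
  )
  sidecar_path <- file.path(out_dir, "simulation.json")
  jsonlite::write_json(sidecar, sidecar_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(markers = marker_paths, trajectory = traj_path,
                 ratings = ratings_path, sidecar = sidecar_path))
}

#' Full naturalness analysis of a rating table
#'
#' Runs the complete analysis against one base trajectory: scores every
#' requested model over the rated conditions, correlates condition-averaged
#' ratings with each model, bootstraps the model-family comparisons
#' (the three trajectory-disparity channels against each other, Bonferroni
#' m = 3; timing against maximum-height error, m = 1), computes
#' per-participant correlations for each model and the pairwise jumper-group
#' comparison for the best model, and sweeps the assumed gravity for the
#' velocity-disparity model.
#'
#' @param ratings Rating table (see [validate_ratings()]).
#' @param base_traj Unmodulated [jump_trajectory()].
#' @param config A [run_config()].
#' @param sweep Logical: run the gravity sweep (default TRUE).
#' @return A list of class `naturalness_report`.
#' @export
analyze_ratings <- function(ratings, base_traj, config = run_config(),
                            sweep = TRUE) {
  validate_ratings(ratings)
  stopifnot(inherits(config, "run_config"))
  grid <- unique(ratings[c("H", "T")])
  grid <- grid[order(grid$H, grid$T), , drop = FALSE]
  means <- average_ratings(ratings)

  grids <- lapply(config$models, function(m) {
    score_grid(base_traj, grid, m, g = config$g)
  })
  names(grids) <- config$models
  correlations <- lapply(grids, function(sg) spearman_correlation(sg, means))

  boot_seed <- derive_seed(config$seed, 3000L)
  comparisons <- list()
  m2 <- c("RMS_height", "RMS_vel", "RMS_acc")
  if (all(m2 %in% config$models)) {
    prs <- utils::combn(m2, 2L)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1L, k]; b <- prs[2L, k]
      comparisons[[paste(a, "vs", b)]] <- bootstrap_corr_difference(
        ratings, grids[[a]], grids[[b]], n_boot = config$n_boot,
        seed = derive_seed(boot_seed, k), n_comparisons = 3L)
    }
  }
  if (all(c("tau_diff_apex", "h_diff") %in% config$models)) {
    comparisons[["tau_diff_apex vs h_diff"]] <- bootstrap_corr_difference(
      ratings, grids[["tau_diff_apex"]], grids[["h_diff"]],
      n_boot = config$n_boot, seed = derive_seed(boot_seed, 10L),
      n_comparisons = 1L)
  }

  per_participant <- lapply(grids, function(sg) per_participant_correlations(ratings, sg))

  rho_abs <- vapply(correlations, function(x) abs(x$rho), numeric(1))
  best_model <- names(which.max(rho_abs))
  per_jumper <- per_jumper_comparison(ratings, grids[[best_model]],
                                      n_boot = min(config$n_boot, 2000L),
                                      seed = derive_seed(boot_seed, 20L))

  sweep_res <- NULL
  if (sweep && "RMS_vel" %in% config$models) {
    key <- cond_key(grid$H, grid$T)
    mm <- means$mean_rating[match(key, cond_key(means$H, means$T))]
    sweep_res <- gravity_sweep(base_traj, grid, mm, g0 = config$g)
  }

  structure(
    list(config = unclass(config),
         version = as.character(utils::packageVersion("jumpnat")),
         n_participants = length(unique(ratings$participant_id)),
         n_conditions = nrow(grid),
         best_model = best_model,
         correlations = correlations,
         comparisons = comparisons,
         per_participant = per_participant,
         per_jumper = per_jumper,
         gravity_sweep = sweep_res,
         score_grids = grids,
         condition_means = means),
    class = "naturalness_report"
  )
}

#' @export
print.naturalness_report <- function(x, ...) {
  cat(sprintf("<naturalness_report> %d participants, %d conditions\n",
              x$n_participants, x$n_conditions))
  for (m in names(x$correlations)) {
    r <- x$correlations[[m]]
    cat(sprintf("  %-14s rho = %+.3f  (p = %.3g)\n", m, r$rho, r$p_value))
  }
  cat(sprintf("  best model by |rho|: %s\n", x$best_model))
  if (!is.null(x$gravity_sweep)) {
    cat(sprintf("  gravity sweep peak: %.3f m/s^2\n", x$gravity_sweep$peak_g))
  }
  invisible(x)
}

#' Run the analysis from files and write its outputs
#'
#' File-level wrapper over [analyze_ratings()]: reads and validates the
#' rating CSV and base-trajectory CSV, runs the analysis, and writes the
#' report JSON plus one score CSV per model.
#'
#' @inheritParams analyze_ratings
#' @param ratings_path Rating-table CSV.
#' @param trajectory_path Base flight-phase trajectory CSV
#'   (`time_s`, `height_m`).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the `naturalness_report`.
#' @export
cmd_analyze <- function(config = run_config(), ratings_path, trajectory_path,
                        out_dir, sweep = TRUE) {
  ratings <- read_ratings_csv(ratings_path)
  base_traj <- read_trajectory_csv(trajectory_path)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory `%s`", out_dir), call. = FALSE)
  }
  report <- analyze_ratings(ratings, base_traj, config, sweep = sweep)
  for (m in names(report$score_grids)) {
    write_score_grid_csv(report$score_grids[[m]],
                         file.path(out_dir, sprintf("scores_%s.csv", m)))
  }
  write_report_json(report, file.path(out_dir, "report.json"))
  invisible(report)
}

#' @rdname cmd_analyze
#' @param report A `naturalness_report`.
#' @param path Output JSON path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "naturalness_report"))
  out <- list(
    package = "jumpnat",
    version = report$version,
    config = report$config,
    n_participants = report$n_participants,
    n_conditions = report$n_conditions,
    best_model = report$best_model,
    correlations = lapply(report$correlations, function(r) {
      list(rho = r$rho, p_value = r$p_value, n = r$n)
    }),
    comparisons = lapply(report$comparisons, function(b) {
      b[c("rho_A", "rho_B", "observed_diff", "p_value", "corrected_p",
          "n_boot", "n_redrawn", "seed")]
    }),
    per_participant = lapply(report$per_participant, function(d) d$rho),
    per_jumper = report$per_jumper,
    gravity_sweep = if (is.null(report$gravity_sweep)) NULL else list(
      model = report$gravity_sweep$model,
      peak_g = report$gravity_sweep$peak_g,
      curve = report$gravity_sweep$curve
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
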