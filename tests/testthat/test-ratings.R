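make_table <- function(ratings_by_participant, grid = grid81,
                       jumpers = NULL) {
  n <- length(ratings_by_participant)
  if (is.null(jumpers)) jumpers <- rep("J01", n)
  do.call(rbind, lapply(seq_len(n), function(p) {
    data.frame(participant_id = sprintf("P%03d", p), jumper_id = jumpers[p],
               H = grid$H, T = grid$T,
               rating = ratings_by_participant[[p]],
               stringsAsFactors = FALSE)
  }))
}

test_that("rating-table validation reports offending rows", {
  tab <- make_table(list(rep(0.5, 81)))
  expect_silent(validate_ratings(tab))
  bad <- tab; bad$rating[13] <- 1.5
  expect_error(validate_ratings(bad), "rows: 13")
  dup <- rbind(tab, tab[1, ])
  expect_error(validate_ratings(dup), "duplicated")
  two <- tab; two$jumper_id[5] <- "J02"
  expect_error(validate_ratings(two), "more than one jumper")
  expect_error(validate_ratings(tab[, -5]), "missing columns: rating")
})

test_that("condition averaging is the arithmetic mean per (H, T)", {
  r <- runif(81)
  single <- make_table(list(r))
  m1 <- average_ratings(single)
  expect_equal(m1$mean_rating, r)
  expect_true(all(m1$n_participants == 1L))
  # two participants with ratings r and 1 - r average to 0.5 everywhere
  sym <- make_table(list(r, 1 - r))
  m2 <- average_ratings(sym)
  expect_equal(m2$mean_rating, rep(0.5, 81))
  expect_true(all(m2$n_participants == 2L))
  expect_error(average_ratings(data.frame()), "empty")
})

test_that("32-participant synthetic means land near their expectations", {
  obs <- observer_model(participant_sd_intercept = 0, participant_sd_slope = 0,
                        noise_sd = 0.1)
  tab <- synth_ratings(base_traj, grid81, obs, n_participants = 32, seed = 21)
  m <- average_ratings(tab)
  truth <- attr(tab, "truth_scores")
  expected <- obs$intercept + obs$slope * truth / max(truth)
  # 3 sigma / sqrt(32) Monte-Carlo band, plus the 1/100 quantisation step
  expect_true(all(abs(m$mean_rating - expected) < 3 * 0.1 / sqrt(32) + 0.005))
})

test_that("identical score grids bootstrap to a null difference", {
  tab <- synth_ratings(base_traj, grid81, observer_model(), n_participants = 8,
                       seed = 2)
  sg <- score_grid(base_traj, grid81, "RMS_vel")
  b <- bootstrap_corr_difference(tab, sg, sg, n_boot = 200, seed = 5)
  expect_equal(b$observed_diff, 0)
  expect_equal(b$p_value, 1)
  expect_equal(b$corrected_p, 1)
})

test_that("bootstrap comparison is deterministic given its seed", {
  tab <- synth_ratings(base_traj, grid81, observer_model(), n_participants = 8,
                       seed = 2)
  a <- score_grid(base_traj, grid81, "RMS_vel")
  b <- score_grid(base_traj, grid81, "RMS_height")
  r1 <- bootstrap_corr_difference(tab, a, b, n_boot = 300, seed = 7)
  r2 <- bootstrap_corr_difference(tab, a, b, n_boot = 300, seed = 7)
  expect_identical(r1, r2)
  r3 <- bootstrap_corr_difference(tab, a, b, n_boot = 300, seed = 8)
  expect_false(identical(r1$p_value, r3$p_value) && identical(r1, r3))
  # p-values are probabilities and correction never shrinks them
  r4 <- bootstrap_corr_difference(tab, a, b, n_boot = 300, seed = 7,
                                  n_comparisons = 3)
  expect_gte(r4$corrected_p, r4$p_value)
  expect_lte(r4$corrected_p, 1)
  expect_equal(r4$p_value, r1$p_value)
})

test_that("per-participant correlations are computed independently", {
  sc <- score_grid(base_traj, grid81, "d_HT")
  s <- sc$score
  dec <- 1 - s / (2 * max(s))          # strictly decreasing in score
  tab <- make_table(list(dec, dec, dec))
  pp <- per_participant_correlations(tab, sc)
  expect_equal(nrow(pp), 3L)
  expect_equal(pp$rho, rep(-1, 3))
  # reversing one participant flips only that rho
  tab2 <- make_table(list(dec, 1 - dec, dec))
  pp2 <- per_participant_correlations(tab2, sc)
  expect_equal(pp2$rho, c(-1, 1, -1))
  # a constant participant yields NA with a warning
  tab3 <- make_table(list(dec, rep(0.4, 81)))
  expect_warning(pp3 <- per_participant_correlations(tab3, sc), "constant")
  expect_true(is.na(pp3$rho[2]))
  expect_equal(pp3$rho[1], -1)
})

test_that("per-participant rho dispersion shrinks as noise vanishes", {
  spread <- vapply(c(0.3, 0.1, 0.0), function(ns) {
    obs <- observer_model(noise_sd = ns, participant_sd_intercept = 0,
                          participant_sd_slope = 0)
    tab <- synth_ratings(base_traj, grid81, obs, n_participants = 12, seed = 31)
    sc <- score_grid(base_traj, grid81, "RMS_vel")
    stats::sd(per_participant_correlations(tab, sc)$rho)
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
  expect_equal(spread[3], 0)
})

test_that("jumper comparison enumerates pairs and respects group structure", {
  obs <- observer_model()
  tab <- synth_ratings(base_traj, grid81, obs, n_participants = 20,
                       n_jumpers = 5, seed = 13)
  sc <- score_grid(base_traj, grid81, "RMS_vel")
  res <- per_jumper_comparison(tab, sc, n_boot = 100, seed = 3)
  expect_equal(nrow(res), choose(5, 2))
  expect_true(all(res$corrected_p >= res$p_value - 1e-12))
  expect_true(all(res$corrected_p <= 1))
  # identical generation process: no pair should be significant
  expect_true(all(res$corrected_p > 0.05))
  # single jumper: empty result
  tab1 <- synth_ratings(base_traj, grid81, obs, n_participants = 4,
                        n_jumpers = 1, seed = 13)
  expect_equal(nrow(per_jumper_comparison(tab1, sc, n_boot = 10, seed = 1)), 0L)
  # a lone participant in a group is excluded with a warning
  tab_small <- rbind(
    synth_ratings(base_traj, grid81, obs, n_participants = 4, n_jumpers = 2,
                  seed = 13),
    {
      solo <- synth_ratings(base_traj, grid81, obs, n_participants = 1,
                            n_jumpers = 1, seed = 14)
      solo$participant_id <- "P999"; solo$jumper_id <- "J99"; solo
    }
  )
  expect_warning(res2 <- per_jumper_comparison(tab_small, sc, n_boot = 50,
                                               seed = 2), "J99")
  expect_equal(nrow(res2), 1L)
})

test_that("model ranking is robust to the averaging order", {
  # heterogeneous participant variances: ranking of model correlations is the
  # same whether we average ratings per condition first, or average
  # per-participant rho values
  obs <- observer_model(participant_sd_intercept = 0.15,
                        participant_sd_slope = 0.3, noise_sd = 0.25)
  tab <- synth_ratings(base_traj, grid81, obs, n_participants = 24, seed = 91)
  m <- average_ratings(tab)
  # models with well-separated correlations; near-tied models (the height vs
  # acceleration disparity channels) are legitimately order-unstable
  models <- c("RMS_height", "RMS_vel", "h_diff")
  by_means <- vapply(models, function(mod) {
    spearman_correlation(score_grid(base_traj, grid81, mod), m)$rho
  }, numeric(1))
  by_participant <- vapply(models, function(mod) {
    mean(per_participant_correlations(tab,
      score_grid(base_traj, grid81, mod))$rho, na.rm = TRUE)
  }, numeric(1))
  expect_identical(order(by_means), order(by_participant))
  expect_identical(names(which.max(abs(by_means))), "RMS_vel")
  expect_identical(names(which.max(abs(by_participant))), "RMS_vel")
})

test_that("rating CSV round-trip validates and preserves values", {
  dir <- withr::local_tempdir()
  tab <- synth_ratings(base_traj, grid81, observer_model(), n_participants = 3,
                       seed = 17)
  p <- file.path(dir, "ratings.csv")
  write_ratings_csv(tab, p)
  back <- read_ratings_csv(p)
  expect_equal(back$rating, tab$rating)
  expect_equal(back$participant_id, tab$participant_id)
  bad <- tab; bad$rating[2] <- 2
  pb <- file.path(dir, "bad.csv")
  utils::write.csv(bad, pb, row.names = FALSE)
  expect_error(read_ratings_csv(pb), "outside")
})
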