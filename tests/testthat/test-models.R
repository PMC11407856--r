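test_that("ratio-deviation statistic vanishes exactly on the theoretical curve", {
  expect_identical(model1_deviation(1, 1), 0)
  expect_equal(model1_deviation(exp(0.35), exp(0.175)), 0)
  expect_equal(model1_deviation(1, exp(0.7)), 0.7)
  expect_equal(model1_deviation(exp(0.7), exp(-0.7)), 1.05)
  expect_error(model1_deviation(-1, 1), "positive")
  expect_error(model1_deviation(1, 0), "positive")
})

test_that("RMS disparities match their pure-projectile closed forms", {
  mod <- modulate(base_traj, H = 1, T = 2)     # g_eff = 2.4525
  fit <- fit_projectile(mod)
  d <- 9.81 - 2.4525
  # continuous limit: |g - g_eff| D / sqrt(3), |g - g_eff|, |g - g_eff| D^2 / (2 sqrt 5)
  expect_equal(rms_disparity(mod, fit, 9.81, "velocity", "continuous"),
               d * 2 / sqrt(3), tolerance = 1e-12)
  expect_equal(rms_disparity(mod, fit, 9.81, "acceleration", "continuous"),
               d, tolerance = 1e-12)
  expect_equal(rms_disparity(mod, fit, 9.81, "height", "continuous"),
               d * 4 / (2 * sqrt(5)), tolerance = 1e-12)
  # sampled values approach the continuous forms at ~1/frame_rate accuracy
  expect_equal(rms_disparity(mod, fit, 9.81, "velocity"), d * 2 / sqrt(3),
               tolerance = 5 / fit$n)
  expect_equal(rms_disparity(mod, fit, 9.81, "velocity"), 8.497,
               tolerance = 0.005)
  expect_equal(rms_disparity(mod, fit, 9.81, "acceleration"), 7.3575,
               tolerance = 0.05)
  expect_error(rms_disparity(mod, fit, 9.81, "speed"), "arg")
})

test_that("sampled RMS disparity converges to the continuous limit", {
  cont <- NULL
  errs <- vapply(c(120, 480, 1920), function(fr) {
    tr <- synth_jump(t_n = 1, frame_rate = fr)
    mod <- modulate(tr, H = 0.7, T = 1.69)
    fit <- fit_projectile(mod)
    abs(rms_disparity(mod, fit, 9.81, "velocity") -
          rms_disparity(mod, fit, 9.81, "velocity", "continuous"))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # error shrinks with frame rate
  expect_lt(errs[3], errs[1] / 4)
})

test_that("timing and height prediction errors match the worked example", {
  mod <- modulate(base_traj, H = 1, T = 2)
  fit <- fit_projectile(mod)
  expect_equal(tau_diff(fit, 9.81, "apex"), 0.75, tolerance = 1e-12)
  expect_equal(tau_diff(fit, 9.81, "full"), 1.5, tolerance = 1e-12)
  # closed-form cross-check (t_n T / 2) |H/T^2 - 1|
  expect_equal(tau_diff(fit, 9.81, "apex"), (1 * 2 / 2) * abs(1 / 4 - 1),
               tolerance = 1e-12)
  expect_equal(h_diff(mod, fit, 9.81),
               fit$v0_prime^2 * abs(1 / (2 * 9.81) - 1 / (2 * fit$g_eff)),
               tolerance = 1e-12)
  expect_equal(h_diff(mod, fit, 9.81), 0.9197, tolerance = 1e-4)
  oncurve <- modulate(base_traj, H = 2.01, T = sqrt(2.01))
  expect_lt(h_diff(oncurve, fit_projectile(oncurve), 9.81), 1e-9)
})

test_that("score_grid zeroes every statistic on the theoretical curve", {
  expect_equal(sum(on_curve81), 5L)   # 5 of the 81 grid points sit on T = sqrt(H)
  for (m in MODEL_NAMES) {
    method <- if (m %in% c("RMS_height", "RMS_vel", "RMS_acc")) "continuous" else "sampled"
    sg <- score_grid(base_traj, grid81, m, method = method)
    expect_true(all(sg$score >= 0))
    expect_lt(max(sg$score[on_curve81]), 1e-9)
    expect_gt(min(sg$score[!on_curve81]), 1e-6)
  }
})

test_that("every statistic increases monotonically away from the curve", {
  for (m in MODEL_NAMES) {
    method <- if (m %in% c("RMS_height", "RMS_vel", "RMS_acc")) "continuous" else "sampled"
    sg <- score_grid(base_traj, grid81, m, method = method)
    dev <- round((log(grid81$T) - 0.5 * log(grid81$H)) / 0.0875)
    # along each H row, scores must increase with |deviation| on either side
    for (h in unique(grid81$H)) {
      row <- sg[grid81$H == h, ]
      rdev <- dev[grid81$H == h]
      ord <- order(rdev)
      s <- row$score[ord]; rd <- rdev[ord]
      expect_true(all(diff(s[rd >= 0]) > 0), info = paste(m, "row H =", h))
      expect_true(all(diff(s[rd <= 0]) < 0), info = paste(m, "row H =", h))
    }
  }
})

test_that("velocity disparity penalises the faster of two mirrored jumps", {
  for (a in c(1.19, 1.42, 1.69, 2.01)) {
    fast <- modulate(base_traj, H = a, T = 1 / a)   # higher jump, shorter time
    slow <- modulate(base_traj, H = 1 / a, T = a)
    s_fast <- rms_disparity(fast, fit_projectile(fast), 9.81, "velocity")
    s_slow <- rms_disparity(slow, fit_projectile(slow), 9.81, "velocity")
    expect_gt(s_fast, s_slow)
  }
})

test_that("timing error is proportional to velocity disparity across the grid", {
  sv <- score_grid(base_traj, grid81, "RMS_vel", method = "continuous")$score
  st <- score_grid(base_traj, grid81, "tau_diff_apex")$score
  off <- !on_curve81
  expect_equal(st[off], sqrt(3) / (2 * 9.81) * sv[off], tolerance = 1e-9)
  # sampled evaluation obeys the identity at 1/frame_rate accuracy
  svs <- score_grid(base_traj, grid81, "RMS_vel")$score
  expect_equal(st[off], sqrt(3) / (2 * 9.81) * svs[off],
               tolerance = 5 / length(base_traj$times))
})

test_that("score_grid names the offending condition on failure", {
  bad <- data.frame(H = c(1, -1), T = c(1, 1))
  expect_error(score_grid(base_traj, bad, "RMS_vel"), "H = -1")
})

test_that("gravity sweep reduces to plain correlation on a single g", {
  sc <- score_grid(base_traj, grid81, "RMS_vel")$score
  means <- 1 - sc / (2 * max(sc))
  sw <- gravity_sweep(base_traj, grid81, means, g_grid = 9.81)
  expect_equal(nrow(sw$curve), 1L)
  expect_equal(sw$curve$rho, spearman_rho_p(sc, means)$rho)
  expect_equal(sw$peak_g, 9.81)
})

test_that("gravity sweep flags undefined correlations on constant ratings", {
  w <- capture_warnings(
    sw <- gravity_sweep(base_traj, grid81, rep(0.5, nrow(grid81)),
                        g_grid = c(4.905, 9.81))
  )
  expect_length(w, 2L)
  expect_match(w, "undefined", all = TRUE)
  expect_true(all(is.na(sw$curve$rho)))
  expect_true(is.na(sw$peak_g))
  expect_error(gravity_sweep(base_traj, grid81, c(1, 2, 3)), "length")
})
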