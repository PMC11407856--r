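#' Naturalness model names
#'
#' The seven naturalness statistics implemented by the package. `d_HT`
#' depends only on the modulation ratios; the others are computed from the
#' modulated trajectory through the modulate -> fit -> statistic chain.
#'
#' @format Character vector of length 7.
#' @export
MODEL_NAMES <- c("d_HT", "RMS_height", "RMS_vel", "RMS_acc",
                 "tau_diff_apex", "tau_diff_full", "h_diff")

#' Deviation of modulation ratios from the theoretical curve
#'
#' The ratio-based naturalness statistic: the absolute log-space distance of
#' a condition (H, T) from the theoretical curve T = sqrt(H),
#' d = |log(T) - log(H) / 2|. It is 0 exactly on the curve, where the
#' modulated jump remains an Earth-gravity projectile, and grows as the
#' implied gravity departs from g. The logarithm reflects the assumption that
#' the sensory response to a modulation ratio is compressive.
#'
#' @param H,T Modulation ratios, positive (vectorised).
#' @return Non-negative numeric vector of deviations (dimensionless).
#' @examples
#' model1_deviation(H = 2.01, T = sqrt(2.01))  # 0
#' model1_deviation(H = 1, T = exp(0.7))       # 0.7
#' @export
model1_deviation <- function(H, T) {
  if (!is.numeric(H) || !is.numeric(T) || any(!is.finite(H)) || any(!is.finite(T)) ||
      any(H <= 0) || any(T <= 0)) {
    stop("modulation ratios must be positive and finite", call. = FALSE)
  }
  # snap to 12 significant digits (with an absolute floor at 1e-12) so that
  # conditions that are mathematically tied -- including points exactly on
  # the theoretical curve -- tie exactly despite log() rounding noise
  d <- abs(log(T) - 0.5 * log(H))
  d[d < 1e-12] <- 0
  signif(d, 12)
}

#' RMS disparity between observed and predicted trajectories
#'
#' The trajectory-matching naturalness statistics. The observer is assumed to
#' (i) extract the initial velocity v0' of the observed jump, (ii) predict
#' the height, velocity or acceleration trajectory of an Earth-gravity
#' projectile launched at v0', and (iii) score the jump by the
#' root-mean-square disparity between observed and predicted channel over the
#' N samples of the trajectory:
#' \deqn{RMS = \sqrt{\sum (obs - pred)^2 / N}.}
#' Observed velocity and acceleration come from finite differences of the
#' sampled heights ([observed_kinematics()]); predicted channels are
#' analytic. With `method = "continuous"` the statistic is instead evaluated
#' in the dense-sampling limit, replacing the observed channel by the fitted
#' projectile (v0', g_eff) and the sample mean by the time integral over the
#' flight; for a ballistic trajectory this gives the closed forms
#' |g - g_eff| D^2 / (2 sqrt(5)), |g - g_eff| D / sqrt(3) and |g - g_eff|
#' for height, velocity and acceleration, with D the flight duration.
#'
#' @param traj The (modulated) [jump_trajectory()] that was observed.
#' @param fit Its [fit_projectile()] fit.
#' @param g Gravitational acceleration used for the prediction, m/s^2.
#' @param channel One of `"height"`, `"velocity"`, `"acceleration"`.
#' @param method `"sampled"` (default; evaluate at the trajectory's own
#'   frames) or `"continuous"` (dense-sampling closed form from the fit).
#' @return Non-negative scalar, in m, m/s or m/s^2 according to the channel.
#' @examples
#' traj <- modulate(synth_jump(t_n = 1), H = 1, T = 2)
#' fit <- fit_projectile(traj)
#' rms_disparity(traj, fit, g = 9.81, channel = "velocity")
#' @export
rms_disparity <- function(traj, fit, g = 9.81,
                          channel = c("height", "velocity", "acceleration"),
                          method = c("sampled", "continuous")) {
  stopifnot(inherits(traj, "jump_trajectory"), inherits(fit, "projectile_fit"))
  if (!is.numeric(g) || length(g) != 1L || g <= 0) {
    stop("`g` must be a positive scalar", call. = FALSE)
  }
  channel <- match.arg(channel)
  method <- match.arg(method)
  if (method == "continuous") {
    d <- abs(g - fit$g_eff)
    D <- fit$flight_duration
    return(switch(channel,
      height = d * D^2 / (2 * sqrt(5)),
      velocity = d * D / sqrt(3),
      acceleration = d
    ))
  }
  pred <- predict_kinematics(projectile_params(fit$v0_prime, g), traj$times)
  obs <- switch(channel,
    height = traj$heights,
    velocity = observed_kinematics(traj)$velocity,
    acceleration = observed_kinematics(traj)$acceleration
  )
  prd <- switch(channel,
    height = pred$height,
    velocity = pred$velocity,
    acceleration = pred$acceleration
  )
  sqrt(mean((obs - prd)^2))
}

#' Prediction error in jump timing
#'
#' The timing-based naturalness statistic: the absolute difference between
#' the time predicted from the extracted initial velocity under gravity `g`
#' and the observed time of the modulated jump. With the `"apex"` convention
#' this compares times to the highest point, |v0'/g - D/2|; with `"full"` it
#' compares full flight times, |2 v0'/g - D| -- exactly twice the apex value,
#' so the two conventions are rank-equivalent and give identical rank
#' correlations with any rating vector.
#'
#' @param fit A [fit_projectile()] fit of the observed jump.
#' @param g Gravitational acceleration assumed by the observer, m/s^2.
#' @param convention `"apex"` (default) or `"full"`.
#' @return Non-negative scalar in seconds.
#' @examples
#' fit <- fit_projectile(modulate(synth_jump(t_n = 1), H = 1, T = 2))
#' tau_diff(fit)                      # 0.75 s
#' tau_diff(fit, convention = "full") # 1.5 s
#' @export
tau_diff <- function(fit, g = 9.81, convention = c("apex", "full")) {
  stopifnot(inherits(fit, "projectile_fit"))
  if (!is.numeric(g) || length(g) != 1L || g <= 0) {
    stop("`g` must be a positive scalar", call. = FALSE)
  }
  convention <- match.arg(convention)
  apex <- abs(fit$v0_prime / g - fit$flight_duration / 2)
  if (convention == "apex") apex else 2 * apex
}

#' Prediction error in maximum jump height
#'
#' The height-based naturalness statistic: the absolute difference between
#' the apex height predicted from the extracted initial velocity under
#' gravity `g`, v0'^2 / (2 g), and the observed maximum height of the
#' modulated jump.
#'
#' @inheritParams rms_disparity
#' @return Non-negative scalar in metres.
#' @examples
#' traj <- modulate(synth_jump(t_n = 1), H = 1, T = 2)
#' h_diff(traj, fit_projectile(traj))  # ~0.9197 m
#' @export
h_diff <- function(traj, fit, g = 9.81) {
  stopifnot(inherits(traj, "jump_trajectory"), inherits(fit, "projectile_fit"))
  if (!is.numeric(g) || length(g) != 1L || g <= 0) {
    stop("`g` must be a positive scalar", call. = FALSE)
  }
  abs(fit$v0_prime^2 / (2 * g) - max(traj$heights))
}

#' Score a condition grid with one naturalness model
#'
#' Applies one of the seven naturalness statistics to every (H, T) condition.
#' For the trajectory-based models each condition runs the full chain: the
#' base trajectory is modulated, its projectile parameters are re-fit, and
#' the statistic is evaluated. `d_HT` needs no trajectory.
#'
#' @param base_traj A [jump_trajectory()] of the unmodulated jump (may be
#'   `NULL` for `model = "d_HT"`).
#' @param conditions Data frame with columns `H`, `T` (see
#'   [condition_grid()]).
#' @param model One of [MODEL_NAMES].
#' @param g Gravitational acceleration for the predictions, m/s^2.
#' @param method RMS evaluation method, passed to [rms_disparity()].
#' @return A data frame of class `model_score_grid` with columns `H`, `T`,
#'   `model`, `score`, `g_used`.
#' @examples
#' grid <- condition_grid()
#' sg <- score_grid(synth_jump(t_n = 1), grid, model = "RMS_vel")
#' head(sg)
#' @export
score_grid <- function(base_traj, conditions, model, g = 9.81,
                       method = c("sampled", "continuous")) {
  conditions <- as_conditions(conditions)
  if (nrow(conditions) == 0L) stop("`conditions` must be non-empty", call. = FALSE)
  model <- match.arg(model, MODEL_NAMES)
  method <- match.arg(method)
  if (model == "d_HT") {
    scores <- model1_deviation(conditions$H, conditions$T)
  } else {
    stopifnot(inherits(base_traj, "jump_trajectory"))
    scores <- vapply(seq_len(nrow(conditions)), function(i) {
      H <- conditions$H[i]; T <- conditions$T[i]
      tryCatch({
        mod <- modulate(base_traj, H, T)
        fit <- fit_projectile(mod)
        switch(model,
          RMS_height = rms_disparity(mod, fit, g, "height", method),
          RMS_vel = rms_disparity(mod, fit, g, "velocity", method),
          RMS_acc = rms_disparity(mod, fit, g, "acceleration", method),
          tau_diff_apex = tau_diff(fit, g, "apex"),
          tau_diff_full = tau_diff(fit, g, "full"),
          h_diff = h_diff(mod, fit, g)
        )
      }, error = function(e) {
        stop(sprintf("condition (H = %.4g, T = %.4g): %s", H, T, conditionMessage(e)),
             call. = FALSE)
      })
    }, numeric(1))
  }
  out <- data.frame(H = conditions$H, T = conditions$T,
                    model = model, score = scores, g_used = g,
                    stringsAsFactors = FALSE)
  class(out) <- c("model_score_grid", "data.frame")
  out
}

#' @rdname score_grid
#' @param score_grid A `model_score_grid` data frame.
#' @param path Output CSV path (columns `H`, `T`, `model`, `score`,
#'   `g_used`).
#' @export
write_score_grid_csv <- function(score_grid, path) {
  utils::write.csv(
    score_grid[c("H", "T", "model", "score", "g_used")], path,
    row.names = FALSE
  )
  invisible(path)
}

#' Heat-map display of a score grid
#'
#' @param x A `model_score_grid` over a factorial (H, T) grid.
#' @param ... Passed to [graphics::image()].
#' @export
plot.model_score_grid <- function(x, ...) {
  hs <- sort(unique(x$H)); ts <- sort(unique(x$T))
  z <- matrix(NA_real_, length(hs), length(ts))
  z[cbind(match(x$H, hs), match(x$T, ts))] <- x$score
  graphics::image(log(hs), log(ts), z, xlab = "log H", ylab = "log T",
                  main = unique(x$model),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::abline(a = 0, b = 0.5, col = "white", lwd = 2)
  invisible(x)
}

#' Sweep the assumed gravitational acceleration
#'
#' Recomputes a trajectory-based model's score grid under a range of assumed
#' gravitational accelerations and correlates each grid with the
#' condition-averaged ratings. If observers predict trajectories with an
#' internal gravity near 9.81 m/s^2, the magnitude of the (negative)
#' correlation should peak near 1 g.
#'
#' @param base_traj A [jump_trajectory()] of the unmodulated jump.
#' @param conditions Data frame with columns `H`, `T`.
#' @param ratings_means Numeric vector of per-condition mean ratings, aligned
#'   row-for-row with `conditions`.
#' @param g_grid Positive gravity values to sweep, m/s^2. Default: 31
#'   log-spaced values spanning 0.5 g to 2 g around `g0`.
#' @param model Trajectory-based model to sweep (default `"RMS_vel"`).
#' @param g0 Reference gravity used to build the default sweep grid.
#' @return An object of class `gravity_sweep`: list with `curve` (data frame
#'   `g`, `rho`, `p_value`) and `peak_g` (the grid value maximising |rho|).
#' @examples
#' grid <- condition_grid()
#' traj <- synth_jump(t_n = 1)
#' means <- 1 - score_grid(traj, grid, "RMS_vel")$score / 20
#' gravity_sweep(traj, grid, means, g_grid = c(4.9, 9.81, 19.6))
#' @export
gravity_sweep <- function(base_traj, conditions, ratings_means,
                          g_grid = NULL, model = "RMS_vel", g0 = 9.81) {
  conditions <- as_conditions(conditions)
  if (is.null(g_grid)) g_grid <- default_g_grid(g0)
  if (any(g_grid <= 0)) stop("`g_grid` values must be positive", call. = FALSE)
  if (length(ratings_means) != nrow(conditions)) {
    stop(sprintf("`ratings_means` has length %d but there are %d conditions",
                 length(ratings_means), nrow(conditions)), call. = FALSE)
  }
  res <- lapply(g_grid, function(g) {
    sc <- score_grid(base_traj, conditions, model, g = g)$score
    if (stats::sd(sc) == 0 || stats::sd(ratings_means) == 0) {
      warning("constant scores or ratings: correlation undefined for g = ", g,
              call. = FALSE)
      return(c(NA_real_, NA_real_))
    }
    r <- spearman_rho_p(sc, ratings_means)
    c(r$rho, r$p_value)
  })
  res <- do.call(rbind, res)
  curve <- data.frame(g = g_grid, rho = res[, 1L], p_value = res[, 2L])
  peak_g <- if (all(is.na(curve$rho))) NA_real_ else
    curve$g[which.max(abs(curve$rho))]
  structure(list(curve = curve, peak_g = peak_g, model = model),
            class = "gravity_sweep")
}

#' @rdname gravity_sweep
#' @param n Number of sweep values.
#' @export
default_g_grid <- function(g0 = 9.81, n = 31L) {
  exp(seq(log(0.5 * g0), log(2 * g0), length.out = n))
}

#' @export
print.gravity_sweep <- function(x, ...) {
  cat(sprintf("<gravity_sweep> %s over %d gravity values; |rho| peaks at g = %.4f m/s^2\n",
              x$model, nrow(x$curve), x$peak_g))
  invisible(x)
}
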