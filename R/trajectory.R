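#' Flight-phase jump trajectory
#'
#' Container for the vertical translation of one jump's flight phase: the
#' airborne segment from takeoff to landing, expressed relative to the takeoff
#' position. The first sample is pinned to (0 s, 0 m) so that a ballistic
#' trajectory through the samples has no intercept term.
#'
#' @param times Numeric vector of sample times in seconds; strictly
#'   increasing, first element 0.
#' @param heights Numeric vector of vertical translation in metres, same
#'   length as `times`; first element 0.
#' @param frame_rate Nominal sampling rate in Hz. Defaults to the reciprocal
#'   median frame interval.
#' @param jumper_id Optional label identifying the jumper.
#'
#' @return An object of class `jump_trajectory`: a list with elements
#'   `times`, `heights`, `frame_rate` and `jumper_id`.
#' @examples
#' traj <- synth_jump(t_n = 1, g = 9.81, frame_rate = 120)
#' range(traj$heights)
#' @export
jump_trajectory <- function(times, heights, frame_rate = NULL, jumper_id = NULL) {
  times <- as.numeric(times)
  heights <- as.numeric(heights)
  if (length(times) != length(heights)) {
    stop("`times` and `heights` must have the same length", call. = FALSE)
  }
  if (length(times) < 3L) {
    stop("a jump trajectory needs at least 3 samples", call. = FALSE)
  }
  if (anyNA(times) || anyNA(heights)) {
    stop("`times` and `heights` must not contain missing values", call. = FALSE)
  }
  if (abs(times[1L]) > 1e-12 || abs(heights[1L]) > 1e-9) {
    stop("trajectory must start at the takeoff origin (time 0, height 0)",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (is.null(frame_rate)) {
    frame_rate <- 1 / stats::median(diff(times))
  }
  structure(
    list(times = times, heights = heights,
         frame_rate = frame_rate, jumper_id = jumper_id),
    class = "jump_trajectory"
  )
}

#' @export
print.jump_trajectory <- function(x, ...) {
  cat(sprintf(
    "<jump_trajectory> %d samples over %.3f s (%.4g Hz)%s\n  peak height %.4f m\n",
    length(x$times), x$times[length(x$times)], x$frame_rate,
    if (is.null(x$jumper_id)) "" else paste0(", jumper ", x$jumper_id),
    max(x$heights)
  ))
  invisible(x)
}

#' Vertical projectile parameters
#'
#' Initial vertical velocity and gravitational acceleration of a vertical
#' projectile h(t) = v0 t - g t^2 / 2. Flight duration is 2 v0 / g and apex
#' height v0^2 / (2 g).
#'
#' @param v0 Initial vertical velocity in m/s, positive.
#' @param g Gravitational acceleration in m/s^2, positive.
#' @return An object of class `projectile_params`.
#' @examples
#' p <- projectile_params(v0 = 4.905, g = 9.81)
#' flight_duration(p)  # 1 s
#' apex_height(p)      # 1.22625 m
#' @export
projectile_params <- function(v0, g = 9.81) {
  stopifnot(is.numeric(v0), is.numeric(g), length(v0) == 1L, length(g) == 1L)
  if (!is.finite(v0) || v0 <= 0) stop("`v0` must be positive", call. = FALSE)
  if (!is.finite(g) || g <= 0) stop("`g` must be positive", call. = FALSE)
  structure(list(v0 = v0, g = g), class = "projectile_params")
}

#' @rdname projectile_params
#' @param params A `projectile_params` object.
#' @export
flight_duration <- function(params) 2 * params$v0 / params$g

#' @rdname projectile_params
#' @export
apex_height <- function(params) params$v0^2 / (2 * params$g)

#' @export
print.projectile_params <- function(x, ...) {
  cat(sprintf("<projectile_params> v0 = %.4f m/s, g = %.4f m/s^2 (flight %.4f s, apex %.4f m)\n",
              x$v0, x$g, flight_duration(x), apex_height(x)))
  invisible(x)
}

#' Theoretical projectile kinematics at given times
#'
#' Evaluates the vertical projectile model at the supplied sample times:
#' height v0 t - g t^2 / 2, velocity v0 - g t, and constant acceleration -g.
#'
#' @param params A [projectile_params()] object.
#' @param times Numeric vector of non-negative times in seconds.
#' @return A data frame with columns `time`, `height`, `velocity`,
#'   `acceleration`.
#' @examples
#' predict_kinematics(projectile_params(4.905, 9.81), c(0, 0.5, 1))
#' @export
predict_kinematics <- function(params, times) {
  stopifnot(inherits(params, "projectile_params"))
  times <- as.numeric(times)
  if (anyNA(times) || any(times < 0)) {
    stop("`times` must be non-negative", call. = FALSE)
  }
  data.frame(
    time = times,
    height = params$v0 * times - 0.5 * params$g * times^2,
    velocity = params$v0 - params$g * times,
    acceleration = rep(-params$g, length(times))
  )
}

#' Modulate a jump trajectory in height and duration
#'
#' Scales the translation heights by the height modulation ratio `H` and the
#' sample times by the duration modulation ratio `T`, as when re-timing and
#' re-scaling a recorded jump. The frame count is unchanged; the nominal
#' frame rate is divided by `T`. A modulated jump remains a valid
#' Earth-gravity projectile exactly when T = sqrt(H) (the theoretical curve);
#' otherwise its effective gravity becomes g H / T^2.
#'
#' @param traj A [jump_trajectory()].
#' @param H Height modulation ratio, positive scalar.
#' @param T Duration modulation ratio, positive scalar.
#' @return The modulated [jump_trajectory()].
#' @examples
#' traj <- synth_jump(t_n = 1)
#' slowed <- modulate(traj, H = 1, T = 2)
#' max(slowed$heights) == max(traj$heights)
#' @export
modulate <- function(traj, H, T) {
  stopifnot(inherits(traj, "jump_trajectory"))
  check_ratio(H, "H")
  check_ratio(T, "T")
  jump_trajectory(
    times = traj$times * T,
    heights = traj$heights * H,
    frame_rate = traj$frame_rate / T,
    jumper_id = traj$jumper_id
  )
}

check_ratio <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("modulation ratio `%s` must be a positive finite scalar", name),
         call. = FALSE)
  }
  invisible(x)
}

#' Projectile parameters of a modulated jump, in closed form
#'
#' Under (H, T) modulation a projectile with parameters (v0, g) becomes a
#' projectile with initial velocity v0 H / T and effective gravity g H / T^2.
#' Useful as the analytic counterpart of [fit_projectile()] on modulated
#' trajectories.
#'
#' @inheritParams predict_kinematics
#' @inheritParams modulate
#' @return A [projectile_params()] with the effective parameters.
#' @examples
#' effective_params(projectile_params(4.905, 9.81), H = 2.01, T = sqrt(2.01))
#' @export
effective_params <- function(params, H, T) {
  stopifnot(inherits(params, "projectile_params"))
  check_ratio(H, "H")
  check_ratio(T, "T")
  projectile_params(v0 = params$v0 * H / T, g = params$g * H / T^2)
}

#' Least-squares projectile fit to an observed trajectory
#'
#' Recovers the initial velocity and effective gravitational acceleration of
#' an observed (possibly modulated) jump by minimising the sum of squared
#' residuals of h(t) = v0' t - g_eff t^2 / 2 over the samples. There is no
#' intercept term: the trajectory is anchored at the takeoff origin. The fit
#' solves the 2x2 normal equations in the basis (t, t^2) directly.
#'
#' @param traj A [jump_trajectory()] with at least 3 samples.
#' @return An object of class `projectile_fit`: list with `v0_prime` (m/s),
#'   `g_eff` (m/s^2), `rms_residual` (m), `flight_duration` (s, the last
#'   sample time) and `n` (number of samples).
#' @examples
#' traj <- synth_jump(t_n = 0.5, g = 9.81)
#' fit_projectile(traj)  # recovers v0 = 2.4525, g = 9.81
#' @export
fit_projectile <- function(traj) {
  stopifnot(inherits(traj, "jump_trajectory"))
  t <- traj$times
  h <- traj$heights
  if (length(t) < 3L) stop("projectile fit needs at least 3 samples", call. = FALSE)
  # normal equations for h ~ a t + b t^2 (no intercept); v0' = a, g_eff = -2 b
  s2 <- sum(t^2); s3 <- sum(t^3); s4 <- sum(t^4)
  r1 <- sum(t * h); r2 <- sum(t^2 * h)
  det <- s2 * s4 - s3^2
  if (!is.finite(det) || det <= 0) {
    stop("degenerate sample times: projectile fit is not identifiable", call. = FALSE)
  }
  a <- (s4 * r1 - s3 * r2) / det
  b <- (s2 * r2 - s3 * r1) / det
  g_eff <- -2 * b
  if (g_eff <= 0) {
    stop(sprintf(
      "fitted effective gravity is non-positive (%.4g m/s^2): trajectory is not ballistic",
      g_eff), call. = FALSE)
  }
  if (a <= 0) {
    stop(sprintf("fitted initial velocity is non-positive (%.4g m/s)", a),
         call. = FALSE)
  }
  resid <- h - a * t - b * t^2
  structure(
    list(v0_prime = a, g_eff = g_eff,
         rms_residual = sqrt(mean(resid^2)),
         flight_duration = t[length(t)],
         n = length(t)),
    class = "projectile_fit"
  )
}

#' @export
print.projectile_fit <- function(x, ...) {
  cat(sprintf(
    "<projectile_fit> v0' = %.4f m/s, g_eff = %.4f m/s^2\n  flight %.4f s, rms residual %.3g m (n = %d)\n",
    x$v0_prime, x$g_eff, x$flight_duration, x$rms_residual, x$n))
  invisible(x)
}

#' Observed kinematics by finite differences
#'
#' Differentiates the sampled heights numerically: central differences in the
#' interior, one-sided forward/backward differences at the two ends.
#' Acceleration is the same operator applied to the velocity estimate. These
#' are the "observed" velocity and acceleration channels used by the
#' trajectory-disparity naturalness statistics; the predicted channels remain
#' analytic.
#'
#' @param traj A [jump_trajectory()].
#' @return A data frame with columns `time`, `height`, `velocity`,
#'   `acceleration`.
#' @export
observed_kinematics <- function(traj) {
  stopifnot(inherits(traj, "jump_trajectory"))
  v <- finite_difference(traj$times, traj$heights)
  a <- finite_difference(traj$times, v)
  data.frame(time = traj$times, height = traj$heights,
             velocity = v, acceleration = a)
}

finite_difference <- function(t, y) {
  n <- length(y)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    d[i] <- (y[i + 1L] - y[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  d
}
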