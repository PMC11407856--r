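#' Synthetic flight-phase jump trajectory
#'
#' Generates a vertical projectile flight phase of duration `t_n` sampled at
#' `frame_rate`, with initial velocity v0 = g t_n / 2 so the jump lands at
#' t_n. A smooth residual (a random mix of low-order sine modes, zero at
#' takeoff and landing) of root-mean-square amplitude `deformation_sd`
#' emulates the small non-ballistic component of a real jumper's centroid
#' motion.
#'
#' @param t_n Flight duration in seconds (the study stimuli are ~1 s).
#' @param g Gravitational acceleration, m/s^2.
#' @param frame_rate Sampling rate in Hz (120 Hz is the usual motion-capture
#'   convention).
#' @param deformation_sd RMS amplitude of the smooth residual, metres.
#' @param seed Optional integer seed (used only when `deformation_sd > 0`).
#' @param jumper_id Label attached to the trajectory.
#' @return A [jump_trajectory()].
#' @examples
#' traj <- synth_jump(t_n = 1, g = 9.81)
#' max(traj$heights)  # 1.22625 at the apex sample
#' @export
synth_jump <- function(t_n = 1, g = 9.81, frame_rate = 120,
                       deformation_sd = 0, seed = NULL,
                       jumper_id = "synthetic") {
  stopifnot(t_n > 0, g > 0, frame_rate > 0, deformation_sd >= 0)
  times <- seq(0, t_n, by = 1 / frame_rate)
  if (times[length(times)] < t_n - 1e-12) times <- c(times, t_n)
  v0 <- g * t_n / 2
  heights <- v0 * times - 0.5 * g * times^2
  if (deformation_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    coefs <- stats::rnorm(3L)
    phase <- outer(times / t_n, 1:3, function(u, k) sin(pi * k * u))
    resid <- drop(phase %*% coefs)
    rms <- sqrt(mean(resid^2))
    if (rms > 0) heights <- heights + resid * (deformation_sd / rms)
  }
  jump_trajectory(times, heights, frame_rate = frame_rate, jumper_id = jumper_id)
}

#' Synthetic point-light marker table
#'
#' Builds a marker-trajectory table around a flight-phase trajectory: a
#' fixed body template of `n_markers` (x, y) marker offsets, translated
#' vertically by the jump heights during flight, with standing (zero
#' translation) padding frames before and after so that flight-phase
#' detection is exercised, plus optional per-frame marker jitter.
#'
#' @param traj A [jump_trajectory()] giving the flight-phase translation.
#' @param n_markers Number of point-light markers (41 in the usual full-body
#'   marker set).
#' @param body_height Template body height in metres.
#' @param jitter_sd Per-frame, per-marker coordinate jitter, metres.
#' @param ground_pad Duration of the standing padding either side, seconds.
#' @param seed Optional integer seed (template layout and jitter).
#' @return Data frame with columns `time_s`, `m01_x`, `m01_y`, ...
#' @examples
#' tab <- synth_marker_table(synth_jump(), seed = 1)
#' ncol(tab)  # 1 + 2 * 41
#' @export
synth_marker_table <- function(traj, n_markers = 41L, body_height = 1.7,
                               jitter_sd = 0, ground_pad = 0.5, seed = NULL) {
  stopifnot(inherits(traj, "jump_trajectory"), n_markers >= 1L,
            body_height > 0, jitter_sd >= 0, ground_pad >= 0)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / traj$frame_rate
  n_pad <- max(3L, ceiling(ground_pad / dt))
  pre_t <- seq_len(n_pad) * dt - dt
  flight_t <- pre_t[n_pad] + dt + traj$times
  post_t <- flight_t[length(flight_t)] + seq_len(n_pad) * dt
  time_s <- c(pre_t, flight_t, post_t)
  translation <- c(rep(0, n_pad), traj$heights, rep(0, n_pad))

  off_x <- stats::runif(n_markers, -0.25, 0.25)
  off_y <- stats::runif(n_markers, 0, body_height)
  n_frames <- length(time_s)
  out <- vector("list", 1L + 2L * n_markers)
  out[[1L]] <- time_s
  nms <- "time_s"
  for (m in seq_len(n_markers)) {
    jx <- if (jitter_sd > 0) stats::rnorm(n_frames, 0, jitter_sd) else 0
    jy <- if (jitter_sd > 0) stats::rnorm(n_frames, 0, jitter_sd) else 0
    out[[2L * m]] <- off_x[m] + jx
    out[[2L * m + 1L]] <- off_y[m] + translation + jy
    nms <- c(nms, sprintf("m%02d_x", m), sprintf("m%02d_y", m))
  }
  names(out) <- nms
  as.data.frame(out)
}

#' Synthetic observer model for rating generation
#'
#' Parameters of the rating-generation process used by [synth_ratings()]:
#' each participant rates a condition as a noisy decreasing linear transform
#' of a chosen ground-truth naturalness statistic (max-normalised over the
#' condition grid), with participant-level random intercept and slope,
#' optional preference for longer stimuli, trial-level Gaussian noise,
#' clipping to \[0, 1\] and quantisation to the 100-step visual-analogue
#' grid.
#'
#' Defaults are calibrated so that, with 32 participants on the 81-condition
#' grid, the truth model's condition-mean correlation magnitude falls around
#' 0.85-0.95, the regime observed for human raters.
#'
#' @param truth_model One of [MODEL_NAMES]; the statistic ratings track.
#' @param slope Rating change per unit of max-normalised score (negative:
#'   larger error means less natural).
#' @param intercept Baseline rating of a perfectly natural jump, in \[0, 1\].
#' @param participant_sd_intercept,participant_sd_slope Between-participant
#'   standard deviations of intercept and slope.
#' @param noise_sd Trial-level rating noise standard deviation.
#' @param duration_bonus Rating increment per second of stimulus duration
#'   (>= 0); emulates the observed preference for longer jumps.
#' @param g Gravitational acceleration the simulated observers assume when
#'   computing the truth statistic, m/s^2.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(truth_model = "RMS_vel", slope = -0.65,
                           intercept = 0.85,
                           participant_sd_intercept = 0.06,
                           participant_sd_slope = 0.15,
                           noise_sd = 0.30, duration_bonus = 0,
                           g = 9.81) {
  truth_model <- match.arg(truth_model, MODEL_NAMES)
  stopifnot(noise_sd >= 0, duration_bonus >= 0, g > 0,
            participant_sd_intercept >= 0, participant_sd_slope >= 0,
            intercept >= 0, intercept <= 1)
  structure(
    list(truth_model = truth_model, slope = slope, intercept = intercept,
         participant_sd_intercept = participant_sd_intercept,
         participant_sd_slope = participant_sd_slope,
         noise_sd = noise_sd, duration_bonus = duration_bonus, g = g),
    class = "observer_model"
  )
}

#' Synthetic participant rating table
#'
#' Simulates the full rating study: `n_participants` observers, each
#' assigned one of `n_jumpers` jumper stimuli as evenly as possible, rate
#' every (H, T) condition once according to the [observer_model()] process.
#' Ratings are clipped to \[0, 1\] and quantised to the 100-step
#' visual-analogue grid.
#'
#' @param base_traj Unmodulated [jump_trajectory()] used to compute the
#'   truth statistic (ignored for `truth_model = "d_HT"`).
#' @param conditions Data frame with columns `H`, `T`.
#' @param observer An [observer_model()].
#' @param n_participants Number of simulated participants (the study design
#'   is 32).
#' @param n_jumpers Number of jumper stimuli (the study design is 5).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A rating table (see [validate_ratings()]), with the per-condition
#'   truth scores attached as attribute `truth_scores`.
#' @examples
#' tab <- synth_ratings(synth_jump(), condition_grid(),
#'                      observer_model(), n_participants = 4, seed = 1)
#' nrow(tab)  # 4 * 81
#' @export
synth_ratings <- function(base_traj, conditions, observer = observer_model(),
                          n_participants = 32L, n_jumpers = 5L, seed = 1L) {
  stopifnot(inherits(observer, "observer_model"),
            n_participants >= 1L, n_jumpers >= 1L)
  conditions <- as_conditions(conditions)
  truth <- score_grid(base_traj, conditions, observer$truth_model, g = observer$g)
  smax <- max(truth$score)
  s_norm <- if (smax > 0) truth$score / smax else truth$score
  # stimulus duration of each modulated jump: flight time scaled by T
  t_n <- if (inherits(base_traj, "jump_trajectory")) {
    base_traj$times[length(base_traj$times)]
  } else 1
  durations <- t_n * conditions$T

  if (!is.null(seed)) set.seed(seed)
  jumper_ids <- sprintf("J%02d", seq_len(n_jumpers))
  assignment <- jumper_ids[rep_len(seq_len(n_jumpers), n_participants)]
  assignment <- sort(assignment)
  n_cond <- nrow(conditions)
  rows <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    icpt <- observer$intercept + stats::rnorm(1L, 0, observer$participant_sd_intercept)
    slp <- observer$slope + stats::rnorm(1L, 0, observer$participant_sd_slope)
    raw <- icpt + slp * s_norm + observer$duration_bonus * durations +
      stats::rnorm(n_cond, 0, observer$noise_sd)
    rating <- round(pmin(1, pmax(0, raw)) * 100) / 100
    rows[[p]] <- data.frame(
      participant_id = sprintf("P%03d", p),
      jumper_id = assignment[p],
      H = conditions$H, T = conditions$T,
      rating = rating, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "truth_scores") <- truth$score
  validate_ratings(out)
  out
}
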