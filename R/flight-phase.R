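#' Extract the flight phase of a jump from a marker table
#'
#' Detects the airborne segment of a jump in a marker-trajectory table and
#' returns its vertical translation as a [jump_trajectory()]. The reference
#' signal is the vertical coordinate of the body centroid (the mean over all
#' markers) or, optionally, a single named marker. Takeoff is the first frame
#' whose reference height exceeds the pre-jump baseline by `threshold` with
#' positive velocity; landing is the symmetric condition at the end of the
#' airborne run. The baseline is the median reference height of the first
#' `baseline_frames` frames. The returned trajectory is shifted so its first
#' sample sits at (0 s, 0 m).
#'
#' @param marker_table Data frame with a `time_s` column plus
#'   `<marker>_x` / `<marker>_y` coordinate columns in metres, one row per
#'   frame (the CSV layout of [read_marker_csv()]).
#' @param reference `"centroid"` (default) or the name of one marker, e.g.
#'   `"m07"`, whose `_y` column is then used directly.
#' @param threshold Takeoff/landing detection threshold above baseline, in
#'   metres. Default 0.01 (1 cm).
#' @param baseline_frames Number of leading frames used for the baseline
#'   median. Default 10.
#' @param jumper_id Optional jumper label attached to the result.
#' @return A [jump_trajectory()] covering the detected flight phase.
#' @examples
#' traj <- synth_jump(t_n = 1)
#' tab <- synth_marker_table(traj, seed = 7)
#' extract_flight_phase(tab)
#' @export
extract_flight_phase <- function(marker_table, reference = "centroid",
                                 threshold = 0.01, baseline_frames = 10L,
                                 jumper_id = NULL) {
  if (!is.data.frame(marker_table) || !"time_s" %in% names(marker_table)) {
    stop("`marker_table` must be a data frame with a `time_s` column", call. = FALSE)
  }
  ycols <- grep("_y$", names(marker_table), value = TRUE)
  if (length(ycols) == 0L) {
    stop("`marker_table` has no `*_y` vertical-coordinate columns", call. = FALSE)
  }
  if (identical(reference, "centroid")) {
    ref <- rowMeans(marker_table[ycols])
  } else {
    col <- paste0(reference, "_y")
    if (!col %in% names(marker_table)) {
      stop(sprintf("reference marker column `%s` not found", col), call. = FALSE)
    }
    ref <- marker_table[[col]]
  }
  tt <- marker_table$time_s
  if (any(diff(tt) <= 0)) stop("`time_s` must be strictly increasing", call. = FALSE)

  baseline <- stats::median(ref[seq_len(min(baseline_frames, length(ref)))])
  airborne <- ref > baseline + threshold
  runs <- rle(airborne)
  n_segments <- sum(runs$values)
  if (n_segments == 0L) {
    stop("no airborne segment detected: reference signal never exceeds baseline + threshold",
         call. = FALSE)
  }
  if (n_segments > 1L) {
    stop(sprintf("found %d disjoint airborne segments; expected exactly 1", n_segments),
         call. = FALSE)
  }
  ends <- cumsum(runs$lengths)
  seg <- which(runs$values)
  i2 <- ends[seg]
  i1 <- i2 - runs$lengths[seg] + 1L
  # takeoff requires upward motion at the first airborne frame
  if (i1 > 1L && ref[i1] <= ref[i1 - 1L]) {
    stop("airborne segment does not start with positive velocity", call. = FALSE)
  }
  if (i2 - i1 + 1L < 3L) {
    stop("airborne segment too short (< 3 frames)", call. = FALSE)
  }
  jump_trajectory(
    times = tt[i1:i2] - tt[i1],
    heights = ref[i1:i2] - ref[i1],
    jumper_id = jumper_id
  )
}

#' Read and write marker-trajectory CSV files
#'
#' Marker tables are plain CSV with a header row: column `time_s` plus
#' `<marker>_x`, `<marker>_y` (and optionally `<marker>_z`) coordinate
#' columns in metres, one row per frame.
#'
#' @param path File path.
#' @return `read_marker_csv()` returns the table as a data frame.
#' @export
read_marker_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(tab)) {
    stop(sprintf("`%s` is not a marker table: missing `time_s` column", path),
         call. = FALSE)
  }
  tab
}

#' @rdname read_marker_csv
#' @param marker_table Data frame in the marker-table layout.
#' @export
write_marker_csv <- function(marker_table, path) {
  utils::write.csv(marker_table, path, row.names = FALSE)
  invisible(path)
}

#' Read and write flight-phase trajectory CSV files
#'
#' Trajectory files are two-column CSV: `time_s`, `height_m`.
#'
#' @param path File path.
#' @param jumper_id Optional jumper label attached to the trajectory on read.
#' @return `read_trajectory_csv()` returns a [jump_trajectory()].
#' @export
read_trajectory_csv <- function(path, jumper_id = NULL) {
  tab <- utils::read.csv(path)
  need <- c("time_s", "height_m")
  if (!all(need %in% names(tab))) {
    stop(sprintf("`%s` must have columns %s", path, paste(need, collapse = ", ")),
         call. = FALSE)
  }
  jump_trajectory(tab$time_s, tab$height_m, jumper_id = jumper_id)
}

#' @rdname read_trajectory_csv
#' @param traj A [jump_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "jump_trajectory"))
  utils::write.csv(
    data.frame(time_s = traj$times, height_m = traj$heights),
    path, row.names = FALSE
  )
  invisible(path)
}
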