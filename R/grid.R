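#' Modulation-condition grid
#'
#' Full factorial grid of (H, T) modulation ratios spaced evenly in log
#' space: exp(k * step) for integer k in \[-half_width, half_width\] on each
#' axis. The defaults give the 9 x 9 = 81-condition design with axis values
#' 0.50, 0.59, 0.70, 0.84, 1.00, 1.19, 1.42, 1.69, 2.01 (two-decimal display
#' labels; the ratios themselves are generated from the exponents, so e.g.
#' exp(0.35) = 1.4191, not 1.42).
#'
#' @param half_width Number of grid steps either side of 1 on each axis.
#' @param step Log-spacing of the axis values.
#' @return A data frame of class `condition_grid` with numeric columns `H`,
#'   `T`, integer index columns `h_index`, `t_index` (1-based along each
#'   axis), and display labels `H_label`, `T_label`.
#' @examples
#' grid <- condition_grid()
#' nrow(grid)            # 81
#' unique(grid$H_label)  # the printed axis values
#' @export
condition_grid <- function(half_width = 4L, step = 0.175) {
  stopifnot(half_width >= 0L, step > 0)
  axis <- grid_axis(half_width, step)
  n <- length(axis)
  g <- expand.grid(h_index = seq_len(n), t_index = seq_len(n))
  out <- data.frame(
    H = axis[g$h_index],
    T = axis[g$t_index],
    h_index = g$h_index,
    t_index = g$t_index,
    H_label = sprintf("%.2f", axis[g$h_index]),
    T_label = sprintf("%.2f", axis[g$t_index]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("condition_grid", "data.frame")
  out
}

#' @rdname condition_grid
#' @export
grid_axis <- function(half_width = 4L, step = 0.175) {
  exp(seq.int(-half_width, half_width) * step)
}

as_conditions <- function(conditions) {
  if (is.data.frame(conditions)) {
    if (!all(c("H", "T") %in% names(conditions))) {
      stop("`conditions` must have columns `H` and `T`", call. = FALSE)
    }
    conditions
  } else {
    stop("`conditions` must be a data frame with columns `H` and `T`", call. = FALSE)
  }
}

#' Test whether conditions lie on the theoretical curve
#'
#' A condition (H, T) lies on the theoretical curve T = sqrt(H) exactly when
#' log(T) - log(H) / 2 vanishes; such modulations preserve the gravitational
#' acceleration implied by the trajectory.
#'
#' @param H,T Modulation ratios (vectorised).
#' @param tol Absolute tolerance on log(T) - log(H) / 2.
#' @return Logical vector.
#' @export
on_theoretical_curve <- function(H, T, tol = 1e-9) {
  abs(log(T) - 0.5 * log(H)) <= tol
}
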