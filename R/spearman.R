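#' Spearman rank correlation with mid-rank ties
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks, with a
#' two-sided p-value from the exact permutation distribution for n <= 8 and
#' from the large-sample t approximation (t = rho sqrt((n-2)/(1-rho^2)) on
#' n - 2 df) otherwise. Rank-based, hence invariant under strictly monotone
#' transforms of either argument.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param exact_max Largest n for which the exact permutation p is used.
#' @return List with `rho`, `p_value`, `n`.
#' @examples
#' spearman_rho_p(1:5, c(0.5, 0.4, 0.45, 0.2, 0.1))  # rho = -0.9
#' @export
spearman_rho_p <- function(x, y, exact_max = 8L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("Spearman correlation needs at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("inputs must not contain missing values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: one input is constant", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- permutations(n)
    rho_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = min(p_value, 1), n = n)
}

# all n! permutations of seq_len(n), one per row (n <= 8 in practice)
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# fast rho for bootstrap loops: Pearson correlation of mid-ranks
rho_of_ranks <- function(rx, y) {
  stats::cor(rx, rank(y))
}

#' Correlate a model score grid with condition-averaged ratings
#'
#' Aligns a model's per-condition scores with condition mean ratings by their
#' (H, T) keys and returns Spearman's rho with a two-sided p-value (see
#' [spearman_rho_p()] for conventions).
#'
#' @param scores A `model_score_grid` from [score_grid()].
#' @param means A `condition_means` data frame from [average_ratings()], or a
#'   numeric vector already aligned row-for-row with `scores`.
#' @return List with `rho`, `p_value`, `n`, `model`.
#' @export
spearman_correlation <- function(scores, means) {
  stopifnot(inherits(scores, "model_score_grid"))
  if (is.numeric(means)) {
    if (length(means) != nrow(scores)) {
      stop("`means` vector must align with the score grid rows", call. = FALSE)
    }
    m <- means
    s <- scores$score
  } else {
    key_s <- cond_key(scores$H, scores$T)
    key_m <- cond_key(means$H, means$T)
    idx <- match(key_s, key_m)
    if (anyNA(idx)) {
      stop(sprintf("%d score conditions have no matching rating condition",
                   sum(is.na(idx))), call. = FALSE)
    }
    m <- means$mean_rating[idx]
    s <- scores$score
  }
  r <- spearman_rho_p(s, m)
  r$model <- unique(scores$model)
  r
}

cond_key <- function(H, T) paste(signif(H, 12), signif(T, 12), sep = "|")
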