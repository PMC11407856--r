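#' Validate a rating table
#'
#' A rating table is long-format trial data: one row per (participant,
#' condition) with columns `participant_id`, `jumper_id`, `H`, `T`, `rating`.
#' Ratings live on the visual-analogue scale in \[0, 1\]. Each participant is
#' assigned exactly one jumper, and rates each condition at most once.
#'
#' @param table Data frame to validate.
#' @return The table, invisibly, if valid; otherwise an error listing the
#'   offending rows.
#' @export
validate_ratings <- function(table) {
  need <- c("participant_id", "jumper_id", "H", "T", "rating")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop(sprintf("rating table missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!is.finite(table$rating) | table$rating < 0 | table$rating > 1)
  if (length(bad)) {
    stop(sprintf("ratings outside [0, 1] at rows: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  jmap <- tapply(as.character(table$jumper_id), as.character(table$participant_id),
                 function(j) length(unique(j)))
  if (any(jmap > 1L)) {
    stop(sprintf("participants mapped to more than one jumper: %s",
                 paste(names(jmap)[jmap > 1L], collapse = ", ")), call. = FALSE)
  }
  key <- paste(table$participant_id, cond_key(table$H, table$T))
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop(sprintf("duplicated (participant, H, T) trials at rows: %s",
                 paste(utils::head(dup, 10L), collapse = ", ")), call. = FALSE)
  }
  invisible(table)
}

#' Condition-averaged ratings
#'
#' Averages trial ratings across participants for each (H, T) condition.
#'
#' @param table A validated rating table (see [validate_ratings()]).
#' @return A data frame of class `condition_means` with columns `H`, `T`,
#'   `mean_rating`, `n_participants`.
#' @export
average_ratings <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("rating table is empty", call. = FALSE)
  }
  validate_ratings(table)
  key <- cond_key(table$H, table$T)
  first <- !duplicated(key)
  out <- data.frame(
    H = table$H[first],
    T = table$T[first],
    mean_rating = as.numeric(tapply(table$rating, key, mean)[key[first]]),
    n_participants = as.integer(tapply(table$rating, key, length)[key[first]])
  )
  class(out) <- c("condition_means", "data.frame")
  out
}

# participants-by-conditions rating matrix aligned to the given score grid
ratings_matrix <- function(table, scores) {
  validate_ratings(table)
  pid <- as.character(table$participant_id)
  participants <- unique(pid)
  key_s <- cond_key(scores$H, scores$T)
  col <- match(cond_key(table$H, table$T), key_s)
  if (anyNA(col)) {
    stop(sprintf("%d rating trials have conditions absent from the score grid",
                 sum(is.na(col))), call. = FALSE)
  }
  M <- matrix(NA_real_, length(participants), length(key_s),
              dimnames = list(participants, key_s))
  M[cbind(match(pid, participants), col)] <- table$rating
  if (anyNA(M)) {
    stop("rating table does not cover every (participant, condition) cell",
         call. = FALSE)
  }
  M
}

participant_jumpers <- function(table) {
  pid <- as.character(table$participant_id)
  jid <- as.character(table$jumper_id)
  jid[match(unique(pid), pid)]
}

#' Bootstrap comparison of two models' rating correlations
#'
#' Tests whether two naturalness models differ in how well they track the
#' ratings. Participants are resampled with replacement; each resample
#' recomputes the condition-averaged ratings and the two Spearman
#' correlations, giving a bootstrap distribution of the rho difference
#' (model A minus model B). The two-sided p-value is
#' 2 min(P(diff <= 0), P(diff >= 0)) with +1 smoothing in numerator and
#' denominator, Bonferroni-corrected by `n_comparisons`. Resamples whose
#' condition means are constant (so rho is undefined) are redrawn and
#' counted.
#'
#' @param table Rating table covering the score-grid conditions.
#' @param scoresA,scoresB `model_score_grid`s over the same conditions.
#' @param n_boot Number of bootstrap resamples (the study convention is
#'   10000).
#' @param seed Integer seed; the same seed reproduces the result exactly.
#' @param n_comparisons Bonferroni correction factor.
#' @return List with `observed_diff` (rho_A - rho_B), `rho_A`, `rho_B`,
#'   `p_value`, `corrected_p`, `n_boot`, `n_redrawn`, `seed`.
#' @export
bootstrap_corr_difference <- function(table, scoresA, scoresB,
                                      n_boot = 10000L, seed = 1L,
                                      n_comparisons = 1L) {
  stopifnot(inherits(scoresA, "model_score_grid"), inherits(scoresB, "model_score_grid"))
  if (n_boot < 1L) stop("`n_boot` must be at least 1", call. = FALSE)
  if (!identical(cond_key(scoresA$H, scoresA$T), cond_key(scoresB$H, scoresB$T))) {
    stop("score grids A and B must cover identical conditions in the same order",
         call. = FALSE)
  }
  M <- ratings_matrix(table, scoresA)
  sA <- scoresA$score; sB <- scoresB$score
  rA <- rank(sA); rB <- rank(sB)
  means <- colMeans(M)
  rho_A <- rho_of_ranks(rA, means)
  rho_B <- rho_of_ranks(rB, means)
  observed <- rho_A - rho_B

  if (!is.null(seed)) set.seed(seed)
  P <- nrow(M)
  diffs <- numeric(n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      m <- colMeans(M[sample.int(P, P, replace = TRUE), , drop = FALSE])
      if (stats::sd(m) > 0) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_boot) {
        stop("bootstrap cannot find a resample with non-constant means", call. = FALSE)
      }
    }
    diffs[b] <- rho_of_ranks(rA, m) - rho_of_ranks(rB, m)
  }
  p <- 2 * min((1 + sum(diffs <= 0)) / (n_boot + 1),
               (1 + sum(diffs >= 0)) / (n_boot + 1))
  p <- min(p, 1)
  list(observed_diff = observed, rho_A = rho_A, rho_B = rho_B,
       p_value = p, corrected_p = min(1, p * n_comparisons),
       n_boot = n_boot, n_redrawn = n_redrawn, seed = seed)
}

#' Per-participant model correlations
#'
#' Spearman's rho between one model's scores and each individual
#' participant's ratings, over the conditions that participant rated.
#' Participants whose ratings are constant get `NA` with a warning.
#'
#' @param table Rating table.
#' @param scores A `model_score_grid`.
#' @return Data frame with columns `participant_id`, `jumper_id`, `rho`, `n`.
#' @export
per_participant_correlations <- function(table, scores) {
  validate_ratings(table)
  pid <- as.character(table$participant_id)
  participants <- unique(pid)
  key_s <- cond_key(scores$H, scores$T)
  out <- lapply(participants, function(p) {
    sub <- table[pid == p, , drop = FALSE]
    idx <- match(cond_key(sub$H, sub$T), key_s)
    keep <- !is.na(idx)
    if (sum(keep) < 3L) {
      stop(sprintf("participant %s rated fewer than 3 score-grid conditions", p),
           call. = FALSE)
    }
    r <- sub$rating[keep]
    s <- scores$score[idx[keep]]
    if (stats::sd(r) == 0 || stats::sd(s) == 0) {
      warning(sprintf("participant %s has constant ratings; rho set to NA", p),
              call. = FALSE)
      rho <- NA_real_
    } else {
      rho <- spearman_rho_p(s, r)$rho
    }
    data.frame(participant_id = p, jumper_id = as.character(sub$jumper_id[1L]),
               rho = rho, n = sum(keep), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pairwise jumper-group comparison of model correlations
#'
#' For each pair of jumper stimuli, bootstraps the difference in group-level
#' Spearman correlation (participants resampled with replacement within each
#' group; group condition means recomputed per resample), with Bonferroni
#' correction over the number of pairs. Groups with fewer than 2 participants
#' are excluded with a warning.
#'
#' @inheritParams bootstrap_corr_difference
#' @param scores A `model_score_grid`.
#' @return Data frame with one row per jumper pair: `jumper_a`, `jumper_b`,
#'   `rho_a`, `rho_b`, `observed_diff`, `p_value`, `corrected_p`. Zero rows
#'   if fewer than 2 usable groups.
#' @export
per_jumper_comparison <- function(table, scores, n_boot = 2000L, seed = 1L) {
  M <- ratings_matrix(table, scores)
  jumper <- participant_jumpers(table)
  counts <- table(jumper)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning(sprintf("excluding jumper group(s) with < 2 participants: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
  }
  groups <- setdiff(names(counts), small)
  empty <- data.frame(jumper_a = character(), jumper_b = character(),
                      rho_a = numeric(), rho_b = numeric(),
                      observed_diff = numeric(), p_value = numeric(),
                      corrected_p = numeric(), stringsAsFactors = FALSE)
  if (length(groups) < 2L) return(empty)

  rS <- rank(scores$score)
  group_rows <- lapply(groups, function(j) which(jumper == j))
  names(group_rows) <- groups
  group_rho <- vapply(group_rows, function(rows) {
    rho_of_ranks(rS, colMeans(M[rows, , drop = FALSE]))
  }, numeric(1))

  pairs <- utils::combn(groups, 2L)
  m_corr <- ncol(pairs)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(seq_len(m_corr), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    ra <- group_rows[[a]]; rb <- group_rows[[b]]
    diffs <- vapply(seq_len(n_boot), function(i) {
      ma <- colMeans(M[sample(ra, length(ra), replace = TRUE), , drop = FALSE])
      mb <- colMeans(M[sample(rb, length(rb), replace = TRUE), , drop = FALSE])
      if (stats::sd(ma) == 0 || stats::sd(mb) == 0) return(NA_real_)
      rho_of_ranks(rS, ma) - rho_of_ranks(rS, mb)
    }, numeric(1))
    diffs <- diffs[!is.na(diffs)]
    nb <- length(diffs)
    p <- 2 * min((1 + sum(diffs <= 0)) / (nb + 1), (1 + sum(diffs >= 0)) / (nb + 1))
    p <- min(p, 1)
    data.frame(jumper_a = a, jumper_b = b,
               rho_a = group_rho[[a]], rho_b = group_rho[[b]],
               observed_diff = group_rho[[a]] - group_rho[[b]],
               p_value = p, corrected_p = min(1, p * m_corr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read and write rating-table CSV files
#'
#' Rating CSVs have columns `participant_id`, `jumper_id`, `H`, `T`,
#' `rating` with ratings in \[0, 1\].
#'
#' @param path File path.
#' @return `read_ratings_csv()` returns the validated rating table.
#' @export
read_ratings_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ratings(tab)
  tab
}

#' @rdname read_ratings_csv
#' @param table Rating table.
#' @export
write_ratings_csv <- function(table, path) {
  validate_ratings(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
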