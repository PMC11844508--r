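# Cross-context correlation and noise ceiling.
#
# At each lag, responses across segments form one vector per (context,
# repetition). The cross-context correlation averages the Pearson
# correlation over all ordered pairs of repetitions across the two
# contexts; the noise ceiling averages it over ordered pairs of distinct
# repetitions within each context, then across contexts. Zero-variance or
# too-sparse columns are dropped from the averages.

MIN_SEGMENTS <- 3L

# mean of a cross-correlation matrix between the columns of A and B,
# masking entries with fewer than MIN_SEGMENTS complete cases; off = TRUE
# drops the diagonal (same-repetition pairs)
mean_colcor <- function(A, B, off_diagonal = FALSE) {
  ok_a <- !is.na(A)
  ok_b <- !is.na(B)
  ncc <- crossprod(ok_a, ok_b) # complete-case counts per column pair
  C <- suppressWarnings(cor(A, B, use = "pairwise.complete.obs"))
  C[ncc < MIN_SEGMENTS] <- NA
  if (off_diagonal) diag(C) <- NA
  if (all(is.na(C))) {
    return(c(value = NA_real_, n_dropped = length(C)))
  }
  c(value = mean(C, na.rm = TRUE), n_dropped = sum(is.na(C)))
}

#' Cross-context correlation profile
#'
#' For each lag, correlates the segment-response vectors across the two
#' contexts over all ordered repetition pairs (including equal repetition
#' indices, which belong to different contexts and are therefore
#' independent) and averages the correlations.
#'
#' @param matrix_set A [build_response_matrix()] result.
#' @return Numeric vector of the correlation at each lag (`NA` where
#'   undefined), with attribute `n_dropped` counting dropped
#'   (zero-variance or too sparse) repetition pairs per lag.
#' @export
cross_context_correlation <- function(matrix_set) {
  M <- matrix_set$M
  n_lag <- dim(M)[2]
  out <- numeric(n_lag)
  dropped <- integer(n_lag)
  for (l in seq_len(n_lag)) {
    res <- mean_colcor(M[, l, 1, , drop = TRUE], M[, l, 2, , drop = TRUE])
    out[l] <- res["value"]
    dropped[l] <- res["n_dropped"]
  }
  attr(out, "n_dropped") <- dropped
  out
}

#' Noise ceiling profile
#'
#' The same correlation computed between distinct repetitions of the same
#' context, averaged over ordered repetition pairs and then over the two
#' contexts: the maximum cross-context correlation attainable given the
#' unit's response variability at each lag.
#'
#' @param matrix_set A [build_response_matrix()] result with >= 2
#'   repetitions.
#' @return Numeric vector over lags.
#' @export
noise_ceiling <- function(matrix_set) {
  M <- matrix_set$M
  if (dim(M)[4] < 2L) abort("noise ceiling needs >= 2 repetitions")
  n_lag <- dim(M)[2]
  out <- numeric(n_lag)
  for (l in seq_len(n_lag)) {
    per_context <- vapply(1:2, function(ci) {
      A <- M[, l, ci, , drop = TRUE]
      mean_colcor(A, A, off_diagonal = TRUE)[["value"]]
    }, numeric(1))
    out[l] <- mean(per_context) # NA if either context undefined
  }
  out
}

#' Tidy cross-context profile of one unit at one duration
#'
#' Computes both the cross-context correlation and the noise ceiling and
#' returns them in long format, ready to pool across durations and units.
#'
#' @param matrix_set A [build_response_matrix()] result.
#' @return A `tci_ccc_profile` tibble with columns `neuron_id`,
#'   `duration`, `lag`, `ccc`, `ceiling`, `n_segments`, `n_reps`.
#' @export
ccc_profile <- function(matrix_set) {
  ccc <- cross_context_correlation(matrix_set)
  ceil <- if (dim(matrix_set$M)[4] >= 2L) {
    noise_ceiling(matrix_set)
  } else {
    rep(NA_real_, length(ccc))
  }
  out <- tibble(
    neuron_id = matrix_set$neuron_id,
    duration = matrix_set$duration,
    lag = matrix_set$lags,
    ccc = as.numeric(ccc),
    ceiling = ceil,
    n_segments = dim(matrix_set$M)[1],
    n_reps = matrix_set$n_reps
  )
  class(out) <- c("tci_ccc_profile", class(tibble()))
  out
}

#' Group-level noise-normalized cross-context correlation
#'
#' Divides the median cross-context correlation over units by the median
#' noise ceiling over units, per lag and duration (and per grouping
#' variable, e.g. cortical region). Lags where the median ceiling falls
#' below `ceiling_floor` are masked: the normalization is unstable there.
#'
#' @param profiles Row-bound [ccc_profile()] tibbles, optionally with
#'   extra grouping columns.
#' @param group Character vector of grouping column names (default none).
#' @param ceiling_floor Minimum median ceiling for a defined ratio.
#' @return Tibble with medians and the `normalized` curve per (group,
#'   duration, lag).
#' @export
group_normalized_ccc <- function(profiles, group = character(), ceiling_floor = 0.05) {
  if (nrow(profiles) == 0) abort("empty profile table")
  profiles %>%
    group_by(across(all_of(c(group, "duration", "lag")))) %>%
    summarise(
      n_units = dplyr::n_distinct(.data$neuron_id),
      ccc_median = median(.data$ccc, na.rm = TRUE),
      ceiling_median = median(.data$ceiling, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      normalized = ifelse(
        is.finite(.data$ceiling_median) & .data$ceiling_median >= ceiling_floor,
        .data$ccc_median / .data$ceiling_median, NA_real_
      )
    )
}
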