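#' Assemble the segment-by-lag response matrices for one duration
#'
#' Extracts, for every shared-segment context pair, the binned response
#' timecourse surrounding each of its two occurrences, aligned to segment
#' onset. The result is the 4-d array `M[i, tau, c, r]`: response to
#' segment (pair) i at lag tau in context c for repetition r. Occurrence
#' onsets are snapped to the nearest bin edge; reported lags are bin
#' centers relative to the nominal segment onset (so the common sub-bin
#' snap offset is reflected in the lag values, not lost). Lags that fall
#' outside the recorded timecourse are `NA`.
#'
#' @param binned A `tci_binned` tibble for a single neuron.
#' @param pairs Context pairs from [enumerate_context_pairs()].
#' @param lag_range Lag window in seconds relative to segment onset;
#'   default `c(-0.1, duration + 0.25)`.
#' @return A `tci_response_matrix`: list with `M` (array pairs x lags x
#'   2 x reps), `lags`, `duration`, `pairs`, `bin_width`, `neuron_id`.
#' @export
build_response_matrix <- function(binned, pairs, lag_range = NULL) {
  stopifnot(inherits(binned, "tci_binned"), nrow(pairs) >= 1)
  if (length(unique(binned$neuron_id)) != 1L) {
    abort("`binned` must contain exactly one neuron; filter first")
  }
  bw <- attr(binned, "bin_width")
  duration <- pairs$duration[1]
  lag_range <- lag_range %||% c(-0.1, duration + 0.25)
  lag_bins <- seq(round(lag_range[1] / bw), round(lag_range[2] / bw))
  reps <- sort(unique(binned$repetition))
  counts_by <- split(binned$counts, binned$sequence_id)
  rep_by <- split(binned$repetition, binned$sequence_id)

  n_pair <- nrow(pairs)
  n_lag <- length(lag_bins)
  n_rep <- length(reps)
  M <- array(NA_real_, dim = c(n_pair, n_lag, 2L, n_rep))
  snap_off <- numeric(2L * n_pair)

  for (ci in 1:2) {
    seq_col <- if (ci == 1) pairs$seq_1 else pairs$seq_2
    on_col <- if (ci == 1) pairs$onset_1 else pairs$onset_2
    onset_bin <- round(on_col / bw)
    snap_off[(ci - 1) * n_pair + seq_len(n_pair)] <- onset_bin * bw - on_col
    for (i in seq_len(n_pair)) {
      sid <- seq_col[i]
      cl <- counts_by[[sid]]
      if (is.null(cl)) abort(sprintf("sequence %s not present in `binned`", sid))
      rr <- rep_by[[sid]]
      idx <- onset_bin[i] + lag_bins + 1L
      ok <- idx >= 1L & idx <= length(cl[[1]])
      for (r in seq_along(rr)) {
        ri <- match(rr[r], reps)
        M[i, ok, ci, ri] <- cl[[r]][idx[ok]]
      }
    }
  }

  structure(
    list(
      M = M,
      lags = lag_bins * bw + bw / 2 + mean(snap_off),
      duration = duration,
      pairs = pairs,
      bin_width = bw,
      neuron_id = binned$neuron_id[1],
      n_reps = n_rep
    ),
    class = "tci_response_matrix"
  )
}

#' @export
print.tci_response_matrix <- function(x, ...) {
  cat(sprintf(
    "<tci_response_matrix %s> %d pairs x %d lags x 2 contexts x %d reps, duration %s ms, bin %.3g ms\n",
    x$neuron_id, dim(x$M)[1], dim(x$M)[2], dim(x$M)[4],
    fmt_ms(x$duration), x$bin_width * 1000
  ))
  invisible(x)
}
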