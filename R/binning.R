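#' Bin spike events into fixed-width count timecourses
#'
#' Counts spikes in contiguous bins `[k*bin_width, (k+1)*bin_width)` tiling
#' `[0, t_end)`. Spikes outside that range are rejected and their number
#' recorded in the `n_rejected` attribute.
#'
#' @param events Tibble of spike events with columns `neuron_id`,
#'   `sequence_id`, `repetition`, `spike_time_s` (as written by
#'   [simulate_response()]).
#' @param bin_width Bin width in seconds (default 5 ms).
#' @param t_end End of the binned range per sequence: a single number, a
#'   named vector (by `sequence_id`), or `NULL` to infer it from the data.
#' @param complete Optional tibble of (`neuron_id`, `sequence_id`,
#'   `repetition`) rows that must appear in the output even with zero
#'   spikes (a repetition without any spike would otherwise be absent).
#' @return A `tci_binned` tibble, one row per (neuron, sequence,
#'   repetition) with a list-column `counts`; attributes `bin_width` and
#'   `n_rejected`.
#' @examples
#' ev <- tibble::tibble(
#'   neuron_id = "n1", sequence_id = "s", repetition = 1L,
#'   spike_time_s = c(0.001, 0.004, 0.011)
#' )
#' bin_spikes(ev, 0.005, t_end = 0.02)$counts[[1]]
#' @export
bin_spikes <- function(events, bin_width = 0.005, t_end = NULL, complete = NULL) {
  stopifnot(bin_width > 0, all(c(
    "neuron_id", "sequence_id", "repetition", "spike_time_s"
  ) %in% names(events)))
  key_cols <- c("neuron_id", "sequence_id", "repetition")
  grid <- dplyr::distinct(as_tibble(events)[, key_cols])
  if (!is.null(complete)) {
    grid <- dplyr::distinct(bind_rows(grid, as_tibble(complete)[, key_cols]))
  }
  grid <- arrange(grid, .data$neuron_id, .data$sequence_id, .data$repetition)
  t_end_for <- function(sid) {
    if (is.null(t_end)) {
      tmax <- max(c(events$spike_time_s[events$sequence_id == sid], 0))
      ceiling((tmax + 1e-9) / bin_width) * bin_width
    } else if (!is.null(names(t_end))) {
      unname(t_end[sid])
    } else {
      t_end
    }
  }
  sids <- unique(grid$sequence_id)
  n_bins_for <- setNames(
    vapply(sids, function(s) as.integer(ceiling(t_end_for(s) / bin_width - 1e-9)), integer(1)),
    sids
  )
  n_rejected <- 0L
  counts <- vector("list", nrow(grid))
  ev_key <- paste(events$neuron_id, events$sequence_id, events$repetition, sep = "\r")
  times_by <- split(events$spike_time_s, ev_key)
  grid_key <- paste(grid$neuron_id, grid$sequence_id, grid$repetition, sep = "\r")
  for (i in seq_len(nrow(grid))) {
    tt <- times_by[[grid_key[i]]] %||% numeric(0)
    nb <- n_bins_for[[grid$sequence_id[i]]]
    bad <- tt < 0 | tt >= nb * bin_width
    n_rejected <- n_rejected + sum(bad)
    counts[[i]] <- tabulate(floor(tt[!bad] / bin_width) + 1L, nbins = nb)
  }
  out <- dplyr::mutate(grid, counts = counts)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_rejected") <- n_rejected
  class(out) <- c("tci_binned", class(tibble()))
  out
}

#' Bin simulated responses (spikes or noiseless rates)
#'
#' Dispatches on the kind of [simulate_response()] output: spike events are
#' counted with [bin_spikes()]; noiseless rate timecourses are integrated
#' (`rate * dt` summed per bin), yielding real-valued expected counts in
#' the same container.
#'
#' @param sim A [simulate_response()] result.
#' @param bin_width Bin width in seconds.
#' @param t_end As in [bin_spikes()].
#' @return A `tci_binned` tibble.
#' @export
bin_response <- function(sim, bin_width = 0.005, t_end = NULL) {
  kind <- attr(sim, "kind") %||%
    (if ("spike_time_s" %in% names(sim)) "spikes" else "rate")
  if (kind == "spikes") {
    return(bin_spikes(sim, bin_width, t_end))
  }
  dt <- attr(sim, "dt")
  out <- sim %>%
    group_by(.data$neuron_id, .data$sequence_id, .data$repetition) %>%
    summarise(counts = {
      te <- if (is.null(t_end)) {
        ceiling((max(.data$time_s) + 1e-9) / bin_width) * bin_width
      } else if (!is.null(names(t_end))) {
        unname(t_end[.data$sequence_id[1]])
      } else {
        t_end
      }
      n_bins <- as.integer(ceiling(te / bin_width - 1e-9))
      # nudge boundary samples consistently upward: grid times sitting on a
      # bin edge must land in the same bin for every occurrence
      b <- pmin(floor(.data$time_s / bin_width + 1e-9) + 1L, n_bins)
      v <- numeric(n_bins)
      acc <- tapply(.data$rate_hz * dt, b, sum)
      v[as.integer(names(acc))] <- as.numeric(acc)
      list(v)
    }, .groups = "drop")
  attr(out, "bin_width") <- bin_width
  attr(out, "n_rejected") <- 0L
  class(out) <- c("tci_binned", class(tibble()))
  out
}

# mean timecourse (concatenated across sequences, sorted by sequence_id)
# over a subset of repetitions
half_timecourse <- function(binned, reps) {
  dat <- binned %>%
    dplyr::filter(.data$repetition %in% reps) %>%
    arrange(.data$sequence_id, .data$repetition)
  sids <- unique(dat$sequence_id)
  unlist(lapply(sids, function(sid) {
    rows <- dat$counts[dat$sequence_id == sid]
    Reduce(`+`, rows) / length(rows)
  }), use.names = FALSE)
}

#' Split-half reliability of a unit's response timecourse
#'
#' Pearson correlation between the mean binned timecourse over odd
#' repetitions and over even repetitions, concatenated across all
#' sequences. Returns `NA` if either half has zero variance (such units
#' fail screening).
#'
#' @param binned A `tci_binned` tibble for one or more neurons (at least
#'   two repetitions each).
#' @return Tibble with columns `neuron_id` and `split_r`.
#' @export
split_half_reliability <- function(binned) {
  purrr::map_dfr(unique(binned$neuron_id), function(nid) {
    b <- dplyr::filter(binned, .data$neuron_id == nid)
    reps <- sort(unique(b$repetition))
    if (length(reps) < 2L) abort("split-half reliability needs >= 2 repetitions")
    odd <- half_timecourse(b, reps[seq_along(reps) %% 2L == 1L])
    even <- half_timecourse(b, reps[seq_along(reps) %% 2L == 0L])
    r <- if (sd(odd) == 0 || sd(even) == 0) NA_real_ else cor(odd, even)
    tibble(neuron_id = nid, split_r = r)
  })
}

#' Permutation p-value for split-half reliability
#'
#' Builds a null distribution by permuting contiguous blocks (default
#' 100 ms) of one half of the data, re-measuring the correlation with the
#' intact half (1000 permutations), fitting a Gaussian to the null
#' correlations, and reporting the upper-tail probability of the observed
#' correlation under that Gaussian. The Gaussian fit makes very small
#' p-values measurable.
#'
#' @param half_1,half_2 Mean binned timecourses of the two repetition
#'   halves (equal-length numeric vectors); blocks of `half_2` are
#'   permuted.
#' @param bin_width Bin width of the timecourses in seconds.
#' @param block Permutation block length in seconds.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutations.
#' @return Scalar p-value (`NA` if the null standard deviation is zero).
#' @export
permutation_pvalue <- function(half_1, half_2, bin_width = 0.005,
                               block = 0.1, n_perm = 1000L, seed = 1L) {
  stopifnot(length(half_1) == length(half_2))
  bsize <- max(1L, round(block / bin_width))
  n_blocks <- floor(length(half_2) / bsize)
  if (n_blocks < 10L) abort("timecourse must span at least 10 permutation blocks")
  if (sd(half_1) == 0 || sd(half_2) == 0) {
    return(NA_real_)
  }
  obs <- cor(half_1, half_2)
  core <- seq_len(n_blocks * bsize)
  blocks <- matrix(half_2[core], nrow = bsize)
  leftover <- half_2[-core]
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm <- c(as.numeric(blocks[, sample(n_blocks)]), leftover)
      cor(half_1, perm)
    }, numeric(1))
  })
  mu <- mean(null_r)
  s <- sd(null_r)
  if (s == 0) {
    return(NA_real_)
  }
  pnorm(obs, mean = mu, sd = s, lower.tail = FALSE)
}

#' Screen units for a reliable response to sound
#'
#' Keeps units whose odd/even split-half correlation is at least
#' `threshold` and significant under the block-permutation test
#' (`p < alpha`). The threshold is 0.1 in the standard design and 0.05 for
#' sparser populations.
#'
#' @param binned A `tci_binned` tibble.
#' @param threshold Minimum split-half correlation (0.1 or 0.05).
#' @param alpha Significance level of the permutation test.
#' @param block,n_perm,seed Passed to [permutation_pvalue()].
#' @return Tibble with `neuron_id`, `split_r`, `p_value`, `reliable`.
#' @export
screen_units <- function(binned, threshold = 0.1, alpha = 1e-5,
                         block = 0.1, n_perm = 1000L, seed = 1L) {
  bin_width <- attr(binned, "bin_width")
  purrr::map_dfr(unique(binned$neuron_id), function(nid) {
    b <- dplyr::filter(binned, .data$neuron_id == nid)
    reps <- sort(unique(b$repetition))
    odd <- half_timecourse(b, reps[seq_along(reps) %% 2L == 1L])
    even <- half_timecourse(b, reps[seq_along(reps) %% 2L == 0L])
    r <- if (sd(odd) == 0 || sd(even) == 0) NA_real_ else cor(odd, even)
    p <- if (is.na(r)) {
      NA_real_
    } else {
      permutation_pvalue(odd, even,
        bin_width = bin_width, block = block,
        n_perm = n_perm, seed = string_seed(nid, seed)
      )
    }
    tibble(
      neuron_id = nid, split_r = r, p_value = p,
      reliable = !is.na(r) && !is.na(p) && r >= threshold && p < alpha
    )
  })
}
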