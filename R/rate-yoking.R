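#' Rate-yoking index
#'
#' Octave difference between the integration windows measured for
#' stretched and compressed stimuli, divided by the octave difference a
#' fully rate-yoked window would show for the given information-rate
#' ratio: `(log2 i_stretched - log2 i_compressed) / log2(factor)`. 0
#' indicates a fixed, time-yoked window; 1 a fully rate-yoked window. The
#' index is not bounded: noise (or a window longer for compressed sounds)
#' can push it outside `[0, 1]`.
#'
#' `factor` is the ratio of information rates between the compressed and
#' stretched conditions. With sounds stretched by 2 and compressed by 2
#' relative to the original, the rate ratio between the two measured
#' conditions is 4 (two octaves); use [yoking_indices()] to derive it from
#' the rate factors directly.
#'
#' @param i_stretched,i_compressed Fitted integration-window widths
#'   (any common unit; the index is unit-invariant).
#' @param factor Information-rate ratio between the two conditions (> 1).
#' @return The dimensionless index (vectorized).
#' @examples
#' rate_yoking_index(0.100, 0.050, factor = 2) # 1: fully rate-yoked
#' rate_yoking_index(0.060, 0.060, factor = 2) # 0: time-yoked
#' @export
rate_yoking_index <- function(i_stretched, i_compressed, factor = 2) {
  if (any(i_stretched <= 0) || any(i_compressed <= 0)) {
    abort("integration windows must be positive")
  }
  if (any(factor <= 1)) abort("`factor` must exceed 1")
  (log2(i_stretched) - log2(i_compressed)) / log2(factor)
}

#' Per-unit yoking indices from fits across stimulus rates
#'
#' Takes window fits per unit and rate factor and computes each unit's
#' rate-yoking index between the slowest (most stretched) and fastest
#' (most compressed) condition, normalized by the actual octave span of
#' the information rates, together with the rate-averaged (geometric mean)
#' width.
#'
#' @param fits Tibble with columns `neuron_id`, `rate_factor`, `width`
#'   (and optionally `split`).
#' @return Tibble with `neuron_id` (and `split` if present),
#'   `width_stretched`, `width_compressed`, `yoking_index`, `mean_width`.
#' @export
yoking_indices <- function(fits) {
  stopifnot(all(c("neuron_id", "rate_factor", "width") %in% names(fits)))
  grp <- intersect(c("neuron_id", "split"), names(fits))
  fits %>%
    group_by(across(all_of(grp))) %>%
    summarise(
      width_stretched = .data$width[which.max(.data$rate_factor)],
      width_compressed = .data$width[which.min(.data$rate_factor)],
      rate_span = max(.data$rate_factor) / min(.data$rate_factor),
      mean_width = exp(mean(log(.data$width))),
      .groups = "drop"
    ) %>%
    mutate(yoking_index = rate_yoking_index(
      .data$width_stretched, .data$width_compressed, .data$rate_span
    )) %>%
    select(-"rate_span")
}

#' Split-half reliability of yoking indices and widths across units
#'
#' Fits obtained on two independent halves of the repetitions give, for
#' each unit and half, a yoking index and a rate-averaged width. This
#' function rank-correlates each quantity across units between the two
#' halves (Spearman) and derives two-sided p-values from a seeded
#' bootstrap over units (resampled correlations centred on their mean form
#' the null).
#'
#' @param fits Tibble with columns `neuron_id`, `rate_factor`, `split`
#'   (1 or 2), `width`; at least 10 units with fits on both splits.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return One-row tibble: `n_units`, `rho_yoking`, `p_yoking`,
#'   `rho_width`, `p_width`.
#' @export
yoking_reliability <- function(fits, n_boot = 1000L, seed = 1L) {
  idx <- yoking_indices(fits)
  wide <- idx %>%
    select("neuron_id", "split", "yoking_index", "mean_width") %>%
    tidyr::pivot_wider(
      names_from = "split",
      values_from = c("yoking_index", "mean_width")
    ) %>%
    dplyr::filter(stats::complete.cases(.))
  if (nrow(wide) < 10L) {
    abort("yoking reliability needs >= 10 units with fits on both splits")
  }
  boot_cor <- function(x, y, stream) {
    obs <- cor(x, y, method = "spearman")
    n <- length(x)
    boots <- with_seed(string_seed(stream, seed), {
      vapply(seq_len(n_boot), function(i) {
        j <- sample.int(n, replace = TRUE)
        suppressWarnings(cor(x[j], y[j], method = "spearman"))
      }, numeric(1))
    })
    boots <- boots[is.finite(boots)]
    centred <- boots - mean(boots)
    p <- (sum(abs(centred) >= abs(obs)) + 1) / (length(centred) + 1)
    c(obs, p)
  }
  yok <- boot_cor(wide$yoking_index_1, wide$yoking_index_2, "yoking")
  wid <- boot_cor(log2(wide$mean_width_1), log2(wide$mean_width_2), "width")
  tibble(
    n_units = nrow(wide),
    rho_yoking = yok[1], p_yoking = yok[2],
    rho_width = wid[1], p_width = wid[2]
  )
}
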