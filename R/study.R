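# End-to-end synthetic study: a population of model neurons with known
# integration windows responding to segment-shuffled sequences, pushed
# through the full estimation pipeline so recovery can be scored against
# ground truth.

#' Specify a synthetic study
#'
#' Defines the stimulus design (sources, tiers, crossfade, repetitions,
#' information-rate factors) and the neural population (groups with
#' log-uniform width ranges, yoking behaviour, nonlinearity, gain). The
#' default is a desk-scale version of the segment-shuffling design: 8
#' sources of 500 ms, 5 duration tiers (500 down to 31.25 ms), 8
#' repetitions, and two groups of 10 neurons whose width ranges mimic
#' primary (15-60 ms) and non-primary (40-150 ms) auditory cortex.
#'
#' @param n_sources,source_duration,top_tier,n_tiers,ramp Stimulus design;
#'   see [build_segment_library()].
#' @param mode Sequence mode, see [generate_sequences()].
#' @param n_reps Stimulus repetitions.
#' @param rate_factors Information-rate factors simulated (e.g.
#'   `c(0.5, 2)` for a stretch/compression experiment). `top_tier` must
#'   divide `source_duration * min(rate_factors)`.
#' @param groups Tibble with columns `group`, `n`, `width_lo`, `width_hi`
#'   (seconds), `yoking`.
#' @param shape True window shape of all neurons.
#' @param nonlinearity,gain,baseline_rate Response model, see
#'   [neuron_spec()].
#' @param center_slack Centers are drawn uniformly between 1 and this
#'   multiple of the minimal causal center.
#' @param bin_width Analysis bin width in seconds.
#' @param master_seed Single seed from which all design, feature and
#'   spiking substreams are derived.
#' @return A `tci_study_spec` list.
#' @export
study_spec <- function(n_sources = 8L, source_duration = 0.5, top_tier = 0.5,
                       n_tiers = 5L, ramp = DEFAULT_RAMP,
                       mode = c("per_duration", "interleaved"),
                       n_reps = 8L, rate_factors = 1,
                       groups = tibble(
                         group = c("primary", "nonprimary"),
                         n = c(10L, 10L),
                         width_lo = c(0.015, 0.040),
                         width_hi = c(0.060, 0.150),
                         yoking = "time_yoked"
                       ),
                       shape = 2L, nonlinearity = "rectify",
                       gain = 120, baseline_rate = 5,
                       center_slack = 1.25,
                       bin_width = 0.005, master_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(
    n_sources >= 1, n_reps >= 1, all(rate_factors > 0),
    all(c("group", "n", "width_lo", "width_hi", "yoking") %in% names(groups)),
    all(groups$width_lo > 0), all(groups$width_hi >= groups$width_lo)
  )
  k <- source_duration * min(rate_factors) / top_tier
  if (abs(k - round(k)) > 1e-9 || round(k) < 1) {
    abort("`top_tier` must divide `source_duration * min(rate_factors)`")
  }
  wr <- window_grid()$widths
  if (any(groups$width_lo < min(wr)) || any(groups$width_hi > max(wr))) {
    abort("group width ranges must lie within the fit grid (1/128 to 0.5 s)")
  }
  structure(
    list(
      n_sources = as.integer(n_sources), source_duration = source_duration,
      top_tier = top_tier, n_tiers = as.integer(n_tiers), ramp = ramp,
      mode = mode, n_reps = as.integer(n_reps), rate_factors = rate_factors,
      groups = groups, shape = as.integer(shape),
      nonlinearity = nonlinearity, gain = gain,
      baseline_rate = baseline_rate, center_slack = center_slack,
      bin_width = bin_width, master_seed = as.integer(master_seed)
    ),
    class = "tci_study_spec"
  )
}

rate_key <- function(rho) sprintf("rate_%s", format(rho))

#' Generate a synthetic study
#'
#' Builds the segment libraries and pseudorandom sequences (one set per
#' rate factor; stretched sources are proportionally longer and subdivide
#' into proportionally more segments), draws the neural population from
#' the group specifications, and simulates spiking responses. Everything
#' is deterministic given `master_seed`.
#'
#' @param spec A [study_spec()].
#' @param noise `"poisson"` or `"none"` (noiseless rates, identical
#'   repetitions).
#' @return A `tci_study` list: `spec`, `truth` (per-neuron ground-truth
#'   table), `libraries` and `sequences` (named by rate factor), `spikes`
#'   (one tibble with a `rate_factor` column).
#' @export
generate_study <- function(spec, noise = c("poisson", "none")) {
  stopifnot(inherits(spec, "tci_study_spec"))
  noise <- match.arg(noise)
  seed0 <- spec$master_seed

  libraries <- list()
  sequences <- list()
  for (rho in spec$rate_factors) {
    src <- source_sounds(spec$n_sources,
      nominal_duration = spec$source_duration * rho, rate_factor = rho
    )
    lib <- build_segment_library(src,
      top_tier = spec$top_tier,
      n_tiers = spec$n_tiers, ramp = spec$ramp
    )
    libraries[[rate_key(rho)]] <- lib
    sequences[[rate_key(rho)]] <- generate_sequences(
      lib, spec$mode,
      seed = string_seed(rate_key(rho), seed0),
      n_repetitions = spec$n_reps
    )
  }

  truth <- with_seed(string_seed("population", seed0), {
    purrr::map_dfr(seq_len(nrow(spec$groups)), function(gi) {
      g <- spec$groups[gi, ]
      w <- exp(runif(g$n, log(g$width_lo), log(g$width_hi)))
      ctr <- minimal_center(w, spec$shape) * runif(g$n, 1, spec$center_slack)
      tibble(
        neuron_id = sprintf("%s_%02d", g$group, seq_len(g$n)),
        group = g$group,
        width = w, center = ctr, shape = spec$shape,
        yoking = g$yoking,
        nonlinearity = spec$nonlinearity,
        gain = spec$gain, baseline_rate = spec$baseline_rate,
        feature_seed = vapply(
          sprintf("%s_%02d|features", g$group, seq_len(g$n)),
          string_seed, integer(1), offset = seed0, USE.NAMES = FALSE
        )
      )
    })
  })

  spikes <- purrr::map_dfr(spec$rate_factors, function(rho) {
    key <- rate_key(rho)
    purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      nrn <- neuron_spec(tr$neuron_id,
        width = tr$width, center = tr$center,
        shape = tr$shape, yoking = tr$yoking,
        nonlinearity = tr$nonlinearity, gain = tr$gain,
        baseline_rate = tr$baseline_rate, feature_seed = tr$feature_seed
      )
      out <- simulate_response(nrn, sequences[[key]], libraries[[key]],
        rate_factor = rho, n_reps = spec$n_reps, noise = noise,
        sim_seed = string_seed(paste0(key, "|spikes"), seed0)
      )
      out$rate_factor <- rho
      out
    })
  })
  attr(spikes, "kind") <- if (noise == "none") "rate" else "spikes"
  attr(spikes, "dt") <- DT_FINE

  structure(
    list(
      spec = spec, truth = truth, libraries = libraries,
      sequences = sequences, spikes = spikes
    ),
    class = "tci_study"
  )
}

#' @export
print.tci_study <- function(x, ...) {
  cat(sprintf(
    "<tci_study> %d neurons x rate factors {%s}; %d sources, %d tiers, %d reps\n",
    nrow(x$truth), paste(format(x$spec$rate_factors), collapse = ", "),
    x$spec$n_sources, x$spec$n_tiers, x$spec$n_reps
  ))
  invisible(x)
}

#' Cross-context profiles for binned responses
#'
#' Convenience pipeline stage: enumerates context pairs and builds the
#' response matrices and [ccc_profile()]s for each neuron and duration.
#'
#' @param binned A `tci_binned` tibble (one or more neurons).
#' @param sequences,library Design objects the responses were recorded to.
#' @param durations Segment durations to analyse (default: all library
#'   tiers presented in `sequences`).
#' @param include_embedded Pool natural-context (embedded) pairs with
#'   random-context pairs (the default maximizes statistical power); set
#'   `FALSE` for random-random pairs only.
#' @param lag_range Passed to [build_response_matrix()].
#' @return Row-bound [ccc_profile()] tibble.
#' @export
ccc_profiles <- function(binned, sequences, library, durations = NULL,
                         include_embedded = TRUE, lag_range = NULL) {
  durations <- durations %||%
    intersect(library$tiers, unique(sequences$tier_duration))
  pair_list <- lapply(durations, function(d) {
    enumerate_context_pairs(sequences, library, d, include_embedded = include_embedded)
  })
  purrr::map_dfr(unique(binned$neuron_id), function(nid) {
    b <- dplyr::filter(binned, .data$neuron_id == nid)
    purrr::map_dfr(seq_along(durations), function(di) {
      m <- build_response_matrix(b, pair_list[[di]], lag_range = lag_range)
      ccc_profile(m)
    })
  })
}

#' Run the estimation pipeline on a synthetic study
#'
#' Bins the spikes, screens units for reliable responses, computes the
#' cross-context profiles and fits the Gamma window of every reliable
#' unit, separately per rate factor (and optionally per odd/even
#' repetition split, for reliability analyses). A single prediction grid
#' is precomputed and shared across all fits.
#'
#' @param study A [generate_study()] result.
#' @param durations Durations to analyse (default: all tiers).
#' @param screen Apply the reliability screen (split-half r and
#'   block-permutation p-value).
#' @param threshold Screening correlation threshold (0.1, or 0.05 for
#'   sparse populations).
#' @param split `"none"` or `"odd_even"`: fit on all repetitions, or
#'   separately on the odd and the even half.
#' @param grid [window_grid()] searched.
#' @param include_embedded Passed to [ccc_profiles()].
#' @return Tibble of fits: `neuron_id`, `rate_factor`, `split`, `width`,
#'   `center`, `shape`, `loss`, plus screening columns.
#' @export
fit_study <- function(study, durations = NULL, screen = TRUE, threshold = 0.1,
                      split = c("none", "odd_even"), grid = window_grid(),
                      include_embedded = TRUE) {
  stopifnot(inherits(study, "tci_study"))
  split <- match.arg(split)
  spec <- study$spec
  fit_grid <- NULL

  purrr::map_dfr(spec$rate_factors, function(rho) {
    key <- rate_key(rho)
    seqs <- study$sequences[[key]]
    lib <- study$libraries[[key]]
    ev <- dplyr::filter(study$spikes, .data$rate_factor == rho)
    te <- with(sequence_durations(seqs), setNames(
      ceiling(duration / spec$bin_width) * spec$bin_width, sequence_id
    ))
    complete <- tidyr::expand_grid(
      neuron_id = study$truth$neuron_id,
      sequence_id = names(te),
      repetition = seq_len(spec$n_reps)
    )
    binned <- if (attr(study$spikes, "kind") == "rate") {
      bin_response(ev, spec$bin_width, t_end = te)
    } else {
      bin_spikes(ev, spec$bin_width, t_end = te, complete = complete)
    }
    scr <- if (screen && spec$n_reps >= 2L) {
      screen_units(binned,
        threshold = threshold,
        seed = string_seed(paste0(key, "|screen"), spec$master_seed)
      )
    } else {
      tibble(
        neuron_id = unique(binned$neuron_id),
        split_r = NA_real_, p_value = NA_real_, reliable = TRUE
      )
    }
    keep <- scr$neuron_id[scr$reliable]

    splits <- if (split == "none") {
      list(list(label = NA_integer_, reps = seq_len(spec$n_reps)))
    } else {
      list(
        list(label = 1L, reps = seq(1, spec$n_reps, by = 2)),
        list(label = 2L, reps = seq(2, spec$n_reps, by = 2))
      )
    }
    purrr::map_dfr(splits, function(sp) {
      bsub <- dplyr::filter(binned, .data$repetition %in% sp$reps)
      attr(bsub, "bin_width") <- spec$bin_width
      purrr::map_dfr(keep, function(nid) {
        prof <- ccc_profiles(
          dplyr::filter(bsub, .data$neuron_id == nid),
          seqs, lib,
          durations = durations, include_embedded = include_embedded
        )
        if (is.null(fit_grid)) {
          fit_grid <<- build_fit_grid(prof, grid = grid, ramp = spec$ramp)
        }
        fit <- fit_window(prof, fit_grid = fit_grid)
        glance(fit) %>%
          mutate(
            rate_factor = rho, split = sp$label,
            split_r = scr$split_r[match(nid, scr$neuron_id)],
            p_value = scr$p_value[match(nid, scr$neuron_id)]
          )
      })
    })
  })
}

#' Score window recovery against ground truth
#'
#' Joins fitted widths to each neuron's true effective width (the
#' generative width, scaled by the rate factor for rate-yoked neurons)
#' and reports signed log2 (octave) errors. Neurons without a fit (e.g.
#' screened out) are kept as `NA` rows, not dropped.
#'
#' @param fits [fit_study()] output (the `split = NA` rows are used if
#'   both are present).
#' @param truth The study's ground-truth table.
#' @return Tibble with per-neuron true and fitted widths and
#'   `error_log2`.
#' @export
score_recovery <- function(fits, truth) {
  f <- fits
  if ("split" %in% names(f) && any(is.na(f$split))) {
    f <- dplyr::filter(f, is.na(.data$split))
  }
  if (!"rate_factor" %in% names(f)) f$rate_factor <- 1
  grid_f <- tidyr::expand_grid(
    neuron_id = truth$neuron_id,
    rate_factor = unique(f$rate_factor)
  )
  grid_f %>%
    left_join(truth[, c("neuron_id", "group", "width", "yoking")], by = "neuron_id") %>%
    mutate(true_width = ifelse(.data$yoking == "rate_yoked",
      .data$width * .data$rate_factor, .data$width
    )) %>%
    left_join(
      f %>% select("neuron_id", "rate_factor",
        fitted_width = "width", "center", "shape", "loss"
      ),
      by = c("neuron_id", "rate_factor")
    ) %>%
    mutate(error_log2 = log2(.data$fitted_width / .data$true_width)) %>%
    select(-"width")
}

#' Summarise recovery errors
#'
#' @param scores A [score_recovery()] table.
#' @return One-row tibble: median signed error, median absolute error,
#'   IQR, and the number of missing fits.
#' @export
recovery_summary <- function(scores) {
  tibble(
    n = nrow(scores),
    n_missing = sum(is.na(scores$error_log2)),
    median_error = median(scores$error_log2, na.rm = TRUE),
    median_abs_error = median(abs(scores$error_log2), na.rm = TRUE),
    iqr_error = stats::IQR(scores$error_log2, na.rm = TRUE)
  )
}
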