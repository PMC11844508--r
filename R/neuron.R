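#' Define a synthetic model neuron
#'
#' A linear-nonlinear Poisson neuron: the latent stimulus drive is filtered
#' by a causal Gamma-shaped integration window, passed through a static
#' nonlinearity, scaled and offset, and (optionally) used as the intensity
#' of Poisson spiking. The true window is known, which is what makes these
#' neurons usable as ground truth for the estimation pipeline.
#'
#' @param neuron_id Identifier.
#' @param width,center,shape True integration-window parameters (seconds,
#'   seconds, integer shape 1-5); see [gamma_window()]. `center = NULL`
#'   uses the minimal causal center for the width and shape.
#' @param yoking `"time_yoked"` (window fixed in absolute time) or
#'   `"rate_yoked"` (width and center scale with the stimulus rate factor).
#' @param nonlinearity `"rectify"` (default), `"identity"`, or
#'   `"exponential"`.
#' @param gain Firing-rate gain in spikes/s per unit drive.
#' @param baseline_rate Baseline firing rate in spikes/s.
#' @param feature_seed Seed of the latent feature realization this neuron
#'   responds to (each neuron has its own receptive field).
#' @return A `tci_neuron` list.
#' @examples
#' neuron_spec("n1", width = 0.03, shape = 2)
#' @export
neuron_spec <- function(neuron_id, width, center = NULL, shape = 2L,
                        yoking = c("time_yoked", "rate_yoked"),
                        nonlinearity = c("rectify", "identity", "exponential"),
                        gain = 100, baseline_rate = 5, feature_seed = 1L) {
  yoking <- match.arg(yoking)
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(width > 0, gain >= 0, baseline_rate >= 0, shape %in% 1:5)
  if (is.null(center)) center <- minimal_center(width, shape)
  if (center < minimal_center(width, shape) - 1e-12) {
    abort("`center` implies an acausal window; the minimal causal center is minimal_center(width, shape)")
  }
  structure(
    list(
      neuron_id = neuron_id, width = width, center = center,
      shape = as.integer(shape), yoking = yoking,
      nonlinearity = nonlinearity, gain = gain,
      baseline_rate = baseline_rate, feature_seed = as.integer(feature_seed)
    ),
    class = "tci_neuron"
  )
}

#' @export
print.tci_neuron <- function(x, ...) {
  cat(sprintf(
    "<tci_neuron %s> width %.3g ms, center %.3g ms, shape %d, %s, %s, gain %.3g, baseline %.3g\n",
    x$neuron_id, x$width * 1000, x$center * 1000, x$shape, x$yoking,
    x$nonlinearity, x$gain, x$baseline_rate
  ))
  invisible(x)
}

# window actually applied at a given stimulus rate
effective_window <- function(neuron, rate_factor, dt = DT_FINE) {
  if (neuron$yoking == "rate_yoked") {
    gamma_window(neuron$width * rate_factor, neuron$center * rate_factor,
      neuron$shape,
      dt = dt
    )
  } else {
    gamma_window(neuron$width, neuron$center, neuron$shape, dt = dt)
  }
}

apply_nonlinearity <- function(x, type) {
  switch(type,
    identity = x,
    rectify = pmax(x, 0),
    exponential = exp(x) - 1
  )
}

#' Simulate spiking (or noiseless rate) responses to sequences
#'
#' Renders each sequence's latent drive, convolves it with the neuron's
#' effective integration window (the true window for a time-yoked neuron;
#' width and center multiplied by `rate_factor` for a rate-yoked one),
#' applies the static nonlinearity, gain and baseline, and draws Poisson
#' spikes per time step and repetition.
#'
#' @param neuron A [neuron_spec()].
#' @param sequences A `tci_sequences` tibble (all sequences are simulated).
#' @param library The segment library behind the sequences.
#' @param rate_factor Stimulus information-rate factor.
#' @param n_reps Number of repetitions.
#' @param noise `"poisson"` for spiking, `"none"` for the deterministic
#'   rate timecourse (repetitions are then identical).
#' @param sim_seed Seed of the spiking noise; repetition r of sequence s is
#'   drawn from an independent substream of it.
#' @param dt Simulation step in seconds (<= 1 ms).
#' @return For `noise = "poisson"`: tibble of spike events with columns
#'   `neuron_id`, `sequence_id`, `repetition`, `spike_time_s` (attribute
#'   `clipped`: number of time steps whose rate was clipped at zero). For
#'   `noise = "none"`: tibble with `neuron_id`, `sequence_id`,
#'   `repetition`, `time_s`, `rate_hz`.
#' @export
simulate_response <- function(neuron, sequences, library, rate_factor = 1,
                              n_reps = 1L, noise = c("poisson", "none"),
                              sim_seed = 1L, dt = DT_FINE) {
  stopifnot(inherits(neuron, "tci_neuron"), dt <= 0.001 + 1e-12)
  noise <- match.arg(noise)
  win <- effective_window(neuron, rate_factor, dt = dt)
  mass <- win$mass # discretized window, sums to 1
  n_clip <- 0L

  seq_ids <- unique(sequences$sequence_id)
  out <- purrr::map_dfr(seq_ids, function(sid) {
    entries <- dplyr::filter(sequences, .data$sequence_id == sid)
    trace <- render_sequence_trace(entries, library,
      rate_factor = rate_factor,
      feature_seed = neuron$feature_seed, dt = dt
    )
    # causal FIR filtering; pad with the silent pre-stimulus period
    x <- c(numeric(length(mass) - 1L), trace$value)
    drive <- stats::filter(x, mass, method = "convolution", sides = 1)
    drive <- as.numeric(drive)[length(mass):length(x)]
    rate <- neuron$baseline_rate +
      neuron$gain * apply_nonlinearity(drive, neuron$nonlinearity)
    neg <- rate < 0
    if (any(neg)) {
      n_clip <<- n_clip + sum(neg)
      rate[neg] <- 0
    }
    if (noise == "none") {
      purrr::map_dfr(seq_len(n_reps), function(r) {
        tibble(
          neuron_id = neuron$neuron_id, sequence_id = sid,
          repetition = as.integer(r), time_s = trace$time, rate_hz = rate
        )
      })
    } else {
      mu <- rate * dt
      purrr::map_dfr(seq_len(n_reps), function(r) {
        s <- string_seed(paste0(neuron$neuron_id, "|", sid, "|", r), sim_seed)
        with_seed(s, {
          counts <- rpois(length(mu), mu)
          nz <- which(counts > 0L)
          if (length(nz) == 0L) {
            return(tibble(
              neuron_id = character(0), sequence_id = character(0),
              repetition = integer(0), spike_time_s = numeric(0)
            ))
          }
          idx <- rep(nz, counts[nz])
          tibble(
            neuron_id = neuron$neuron_id, sequence_id = sid,
            repetition = as.integer(r),
            spike_time_s = sort((idx - 1L) * dt + runif(length(idx)) * dt)
          )
        })
      })
    }
  })
  attr(out, "clipped") <- n_clip
  attr(out, "kind") <- if (noise == "none") "rate" else "spikes"
  attr(out, "dt") <- dt
  out
}
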