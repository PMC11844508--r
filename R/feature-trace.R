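# Latent stimulus feature traces.
#
# Each source sound is represented by a band-limited latent drive: a random
# Fourier series with component frequencies below ~50 Hz (at rate factor 1),
# zero mean and unit variance in expectation. The series is a continuous
# function of content time, so stretched/compressed versions (rate factor
# rho) are evaluated exactly as the rho-time-scaled function -- same
# content, different speed -- with no resampling error, and a segment
# embedded in its parent carries exactly the trace it has when presented
# directly.

N_FOURIER <- 64
F_MAX <- 50 # Hz cutoff at rate factor 1
F_MIN <- 1 # longest modulation a 500 ms source can carry

# continuous feature function of canonical (rate-1) content time
source_feature_fun <- function(source_id, feature_seed = 1L) {
  s <- string_seed(source_id, feature_seed)
  pars <- with_seed(s, {
    list(
      f = runif(N_FOURIER, F_MIN, F_MAX),
      phi = runif(N_FOURIER, 0, 2 * pi)
    )
  })
  amp <- sqrt(2 / N_FOURIER)
  function(t) {
    out <- numeric(length(t))
    for (k in seq_len(N_FOURIER)) {
      out <- out + cos(2 * pi * pars$f[k] * t + pars$phi[k])
    }
    amp * out
  }
}

#' Latent feature trace of one segment
#'
#' Evaluates the seeded band-limited latent drive of a segment on a uniform
#' time grid. For rate factor `rho` the trace is the `rho`-time-scaled
#' version of the rate-1 trace of the same content (a rate-2 trace lasts
#' twice as long and is the rate-1 trace slowed down by 2).
#'
#' @param segment_id Segment identifier (seeds the trace together with
#'   `feature_seed` via `source_id`).
#' @param duration Trace duration in seconds (at the requested rate).
#' @param rate_factor Information-rate factor (1 original, 2 stretched,
#'   0.5 compressed).
#' @param feature_seed Integer seed for the feature realization.
#' @param dt Grid step in seconds (must be <= 1 ms).
#' @param source_id Source the segment is cut from; defaults to the segment
#'   id itself for standalone use. Segments cut from the same source share
#'   one underlying continuous function, which is what makes embedded and
#'   direct presentations of a segment carry identical content.
#' @param onset_in_source Offset of the segment within the source, in
#'   source time at the requested rate.
#' @return A tibble with columns `time` and `value`.
#' @examples
#' tr <- segment_feature_trace("seg1", 0.5, feature_seed = 2)
#' sd(tr$value)
#' @export
segment_feature_trace <- function(segment_id, duration, rate_factor = 1,
                                  feature_seed = 1L, dt = DT_FINE,
                                  source_id = segment_id, onset_in_source = 0) {
  stopifnot(dt <= 0.001 + 1e-12, duration > 0, rate_factor > 0)
  fun <- source_feature_fun(source_id, feature_seed)
  times <- seq(0, duration, by = dt)
  tibble(
    time = times,
    value = fun((onset_in_source + times) / rate_factor)
  )
}

#' Render the latent drive of a whole sequence
#'
#' Concatenates the per-segment feature traces of one presentation sequence,
#' mixing adjacent segments across each crossfade with the same
#' raised-cosine weights used for the stimuli, so context leakage at
#' segment boundaries matches the experimental design.
#'
#' @param sequence Rows of a `tci_sequences` tibble for a single
#'   `sequence_id`.
#' @param library The segment library.
#' @param rate_factor Information-rate factor of the rendered stimulus.
#'   The library is assumed to have been built for this rate (source
#'   `nominal_duration` scales with it).
#' @param feature_seed Seed shared with [segment_feature_trace()].
#' @param dt Grid step in seconds.
#' @return Tibble with columns `time` and `value` covering `[0, T]` where
#'   `T` is the sequence duration.
#' @export
render_sequence_trace <- function(sequence, library, rate_factor = 1,
                                  feature_seed = 1L, dt = DT_FINE) {
  stopifnot(length(unique(sequence$sequence_id)) == 1L)
  ramp <- library$ramp
  segs <- library$segments
  idx <- match(sequence$segment_id, segs$segment_id)
  if (anyNA(idx)) abort("sequence contains segments not in the library")
  t_end <- max(sequence$onset + sequence$tier_duration) + ramp / 2
  n <- floor(t_end / dt) + 1L
  times <- (seq_len(n) - 1L) * dt
  total <- numeric(n)

  funs <- new.env(parent = emptyenv()) # one closure per source
  for (k in seq_len(nrow(sequence))) {
    seg <- segs[idx[k], ]
    o <- sequence$onset[k]
    d <- sequence$tier_duration[k]
    lo <- max(1L, floor((o - ramp / 2) / dt) + 1L)
    hi <- min(n, ceiling((o + d + ramp / 2) / dt) + 1L)
    tt <- times[lo:hi]
    key <- seg$source_id
    if (is.null(funs[[key]])) funs[[key]] <- source_feature_fun(key, feature_seed)
    vals <- funs[[key]]((seg$onset_in_source + (tt - o)) / rate_factor)
    w <- tapered_boxcar(tt - o, d, ramp)
    total[lo:hi] <- total[lo:hi] + w * vals
  }
  tibble(time = times, value = total)
}
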