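# Predicting the cross-context correlation from window-segment overlap,
# and fitting window parameters by grid search.
#
# The overlap of a window with a segment at lag tau is the convolution of
# the discretized window with a boxcar spanning the segment, edge-tapered
# with the raised-cosine crossfade (Hann) ramp. The predicted CCC
# multiplies the noise ceiling by s_shared^2 / (s_shared^2 + sum_n
# s_n,surround^2), where the surrounding segments tile the lag axis on both
# sides of the shared one. Because the surrounds are shifted copies of the
# shared segment, the denominator is an exact periodic fold of s^2 with
# period equal to the segment duration.

# overlap curve s(k*dt) on the fine lag grid; left-edge tap convention
# (cell j of the window acts at lag (k_lo + j - 1)*dt), matching the FIR
# filtering in simulate_response()
s_support <- function(window, duration, ramp) {
  dt <- window$dt
  m0 <- floor((-ramp / 2) / dt)
  m1 <- ceiling((duration + ramp / 2) / dt)
  b <- tapered_boxcar((m0:m1) * dt, duration, ramp)
  s <- convolve(window$mass, rev(b), type = "open")
  list(s = pmin(pmax(s, 0), 1), k0 = window$k_lo + m0)
}

# periodic fold of s^2 with period p cells
fold_s2 <- function(s_sup, p) {
  s2 <- s_sup$s^2
  idx <- ((s_sup$k0 + seq_along(s2) - 1L) %% p) + 1L
  out <- numeric(p)
  rs <- rowsum(s2, idx)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

interp_periodic <- function(y, dt, q) {
  p <- length(y)
  pos <- (q / dt) %% p
  i0 <- floor(pos)
  frac <- pos - i0
  y[(i0 %% p) + 1L] * (1 - frac) + y[((i0 + 1L) %% p) + 1L] * frac
}

#' Overlap of an integration window with a segment
#'
#' `s(tau) = (h * b)(tau)`: the discretized window convolved with a boxcar
#' covering the segment `[0, duration]`, with raised-cosine tapers of total
#' length `ramp` centred on both edges (weight 0.5 at the nominal
#' boundary, mirroring the stimulus crossfade).
#'
#' @param window A [gamma_window()].
#' @param duration Segment duration in seconds.
#' @param lags Lags (seconds, relative to segment onset) at which to
#'   evaluate the overlap.
#' @param ramp Crossfade ramp in seconds.
#' @return Numeric vector in `[0, 1]`, one value per lag.
#' @export
segment_overlap <- function(window, duration, lags, ramp = DEFAULT_RAMP) {
  sup <- s_support(window, duration, ramp)
  interp_uniform(sup$s, sup$k0 * window$dt, window$dt, lags, fill = 0)
}

#' Predicted cross-context correlation for a window
#'
#' Multiplies the noise ceiling by the relative squared overlap of the
#' window with the shared segment versus the surrounding segments
#' (same-duration segments tiling the lag axis on both sides):
#' `P(tau) = ceiling(tau) * s_shared(tau)^2 / (s_shared(tau)^2 +
#' sum_n s_surround_n(tau)^2)`, with the ratio defined as 0 where the
#' denominator vanishes.
#'
#' @param window A [gamma_window()].
#' @param duration Shared-segment duration in seconds.
#' @param lags Lags at which to predict.
#' @param ceiling Noise ceiling: scalar or vector over lags (1 for a
#'   noiseless response).
#' @param ramp Crossfade ramp in seconds.
#' @return Numeric vector of predicted correlations.
#' @export
predict_ccc <- function(window, duration, lags, ceiling = 1, ramp = DEFAULT_RAMP) {
  dt <- window$dt
  p <- round(duration / dt)
  if (abs(p * dt - duration) > 1e-9) {
    abort("`duration` must be an integer multiple of the window grid step")
  }
  sup <- s_support(window, duration, ramp)
  s2p <- fold_s2(sup, p)
  shared <- interp_uniform(sup$s, sup$k0 * dt, dt, lags, fill = 0)
  denom <- interp_periodic(s2p, dt, lags)
  ratio <- ifelse(denom > 0, shared^2 / denom, 0)
  rep_len(ceiling, length(lags)) * ratio
}

#' Parameter grid for window fitting
#'
#' The default grid spans 100 logarithmically spaced widths from 1/128 to
#' 0.5 s, 100 logarithmically spaced centers from 1 ms to 0.25 s, and
#' shapes 1-5. Combinations implying an acausal window are excluded at fit
#' time.
#'
#' @param n_width,width_range,n_center,center_range,shapes Grid controls.
#' @return A `tci_window_grid` list.
#' @export
window_grid <- function(n_width = 100L, width_range = c(1 / 128, 0.5),
                        n_center = 100L, center_range = c(0.001, 0.25),
                        shapes = 1:5) {
  structure(
    list(
      widths = exp(seq(log(width_range[1]), log(width_range[2]), length.out = n_width)),
      centers = exp(seq(log(center_range[1]), log(center_range[2]), length.out = n_center)),
      shapes = as.integer(shapes)
    ),
    class = "tci_window_grid"
  )
}

#' Precompute the prediction grid for a set of durations and lags
#'
#' Evaluates the overlap ratio `s_shared^2 / sum s^2` for every parameter
#' combination of the grid at every (duration, lag) of the supplied
#' profiles. Building this once and reusing it across units makes each fit
#' two matrix-vector products. Within a (shape, width) the overlap curve
#' is computed once and shifted for each center (the center only moves the
#' window shift `delta`), which keeps the precomputation itself cheap.
#'
#' @param profiles A [ccc_profile()] tibble (or several row-bound ones)
#'   whose distinct (duration, lag) pairs define the prediction points.
#' @param grid A [window_grid()].
#' @param ramp Crossfade ramp in seconds.
#' @param dt Fine grid step for the overlap computation.
#' @return A `tci_fit_grid` object.
#' @export
build_fit_grid <- function(profiles, grid = window_grid(), ramp = DEFAULT_RAMP,
                           dt = DT_FINE) {
  key <- profiles %>%
    dplyr::distinct(.data$duration, .data$lag) %>%
    arrange(.data$duration, .data$lag)
  durations <- unique(key$duration)
  n_w <- length(grid$widths)
  n_c <- length(grid$centers)
  n_s <- length(grid$shapes)
  n_combo <- n_w * n_c * n_s
  n_col <- nrow(key)
  col_rows <- lapply(durations, function(d) which(abs(key$duration - d) < 1e-12))

  ratio_t <- matrix(0, nrow = n_col, ncol = n_combo)
  causal <- logical(n_combo)
  delta_of <- numeric(n_combo)
  # combo index: width slowest, then center, then shape (ties in the fit
  # therefore break toward smaller width, then center, then shape)
  combo_idx <- function(wi, ci, si) ((wi - 1L) * n_c + (ci - 1L)) * n_s + si

  for (si in seq_len(n_s)) {
    shape <- grid$shapes[si]
    bs <- baseline_gamma_stats(shape)
    for (wi in seq_len(n_w)) {
      w <- grid$widths[wi]
      lambda <- w / bs$w_d
      deltas <- grid$centers - lambda * bs$c_d
      ok <- deltas >= -dt / 2
      cols <- combo_idx(wi, seq_len(n_c), si)
      causal[cols] <- ok
      delta_of[cols] <- deltas
      if (!any(ok)) next
      win0 <- gamma_window(w, lambda * bs$c_d, shape, dt = dt) # delta = 0
      for (di in seq_along(durations)) {
        d <- durations[di]
        p <- round(d / dt)
        sup <- s_support(win0, d, ramp)
        s2p <- fold_s2(sup, p)
        lags_d <- key$lag[col_rows[[di]]]
        q <- outer(lags_d, deltas[ok], `-`) # lag - delta
        shared <- interp_uniform(sup$s, sup$k0 * dt, dt, as.numeric(q), fill = 0)
        denom <- interp_periodic(s2p, dt, as.numeric(q))
        r <- ifelse(denom > 0, shared^2 / denom, 0)
        ratio_t[col_rows[[di]], cols[ok]] <- r
      }
    }
  }

  structure(
    list(
      key = key,
      grid = grid,
      ramp = ramp,
      dt = dt,
      combos = tidyr::expand_grid(
        width = grid$widths, center = grid$centers, shape = grid$shapes
      ) %>% mutate(delta = delta_of, causal = causal),
      ratio_t = ratio_t,
      ratio2_t = ratio_t^2
    ),
    class = "tci_fit_grid"
  )
}

#' @export
print.tci_fit_grid <- function(x, ...) {
  cat(sprintf(
    "<tci_fit_grid> %d parameter combinations x %d (duration, lag) points; durations %s ms\n",
    nrow(x$combos), nrow(x$key),
    paste(fmt_ms(unique(x$key$duration)), collapse = "/")
  ))
  invisible(x)
}

#' Fit a Gamma integration window to cross-context profiles
#'
#' Grid search over window width, center and shape minimizing the summed
#' squared difference between the measured cross-context correlation and
#' its prediction from the noise ceiling and the window-segment overlaps,
#' pooled over all durations and defined lags. Acausal parameter
#' combinations are excluded; exact ties break toward the smaller width,
#' then smaller center, then smaller shape.
#'
#' @param profiles Row-bound [ccc_profile()] tibbles of one unit covering
#'   at least two segment durations.
#' @param fit_grid Optional precomputed [build_fit_grid()] (must match the
#'   profiles' durations and lags); built on the fly when `NULL`.
#' @param grid,ramp,dt Used when building the fit grid.
#' @param ceiling_weighted If `TRUE`, weight each lag's squared error by
#'   its squared noise ceiling (down-weighting unreliable lags); default
#'   is the unweighted pooled SSE.
#' @param lag_window Optional `c(lo, hi)` restricting, per duration, the
#'   fitted lags to `duration + lag_window` (default: all defined lags).
#' @return A `tci_window_fit` list: `width`, `center`, `shape`, `loss`,
#'   `window` (the best [gamma_window()]), `predictions` (per duration and
#'   lag: observed and predicted), `n_durations`, `n_points`.
#' @export
fit_window <- function(profiles, fit_grid = NULL, grid = window_grid(),
                       ramp = DEFAULT_RAMP, dt = DT_FINE,
                       ceiling_weighted = FALSE, lag_window = NULL) {
  prof <- profiles %>%
    arrange(.data$duration, .data$lag)
  if (length(unique(prof$duration)) < 2L) {
    abort("fit_window() needs profiles from at least 2 segment durations")
  }
  if (is.null(fit_grid)) {
    fit_grid <- build_fit_grid(prof, grid = grid, ramp = ramp, dt = dt)
  }
  key <- fit_grid$key
  if (nrow(prof) != nrow(key) ||
    max(abs(prof$duration - key$duration)) > 1e-9 ||
    max(abs(prof$lag - key$lag)) > 1e-9) {
    abort("`fit_grid` was built for different durations/lags than `profiles`")
  }
  y <- prof$ccc
  ce <- prof$ceiling
  defined <- is.finite(y) & is.finite(ce)
  if (!is.null(lag_window)) {
    defined <- defined &
      prof$lag >= lag_window[1] & prof$lag <= prof$duration + lag_window[2]
  }
  wt <- if (ceiling_weighted) ce^2 else rep(1, length(y))
  y0 <- ifelse(defined, y, 0)
  c0 <- ifelse(defined, ce, 0)
  w0 <- ifelse(defined, wt, 0)

  # SSE_j = sum_i w_i (ratio_ij c_i - y_i)^2, expanded into two
  # matrix-vector products plus a constant
  loss <- as.numeric(crossprod(fit_grid$ratio2_t, w0 * c0^2)) -
    2 * as.numeric(crossprod(fit_grid$ratio_t, w0 * c0 * y0)) +
    sum(w0 * y0^2)
  loss[!fit_grid$combos$causal] <- Inf
  if (all(!is.finite(loss))) abort("no causal grid point could be evaluated")
  best <- which.min(loss)
  bw <- fit_grid$combos$width[best]
  bc <- fit_grid$combos$center[best]
  bshape <- fit_grid$combos$shape[best]

  preds <- prof %>%
    mutate(
      predicted = fit_grid$ratio_t[, best] * .data$ceiling,
      used = defined
    )
  structure(
    list(
      neuron_id = if ("neuron_id" %in% names(prof)) prof$neuron_id[1] else NA_character_,
      width = bw, center = bc, shape = bshape,
      loss = loss[best],
      window = gamma_window(bw, bc, bshape, dt = fit_grid$dt),
      predictions = preds,
      n_durations = length(unique(prof$duration)),
      n_points = sum(defined)
    ),
    class = "tci_window_fit"
  )
}

#' @export
print.tci_window_fit <- function(x, ...) {
  cat(sprintf(
    "<tci_window_fit %s> width %.4g ms, center %.4g ms, shape %d; loss %.4g over %d points (%d durations)\n",
    x$neuron_id, x$width * 1000, x$center * 1000, x$shape, x$loss,
    x$n_points, x$n_durations
  ))
  invisible(x)
}

#' @describeIn fit_window One row per fitted parameter.
#' @param x A `tci_window_fit`.
#' @param ... Unused.
#' @method tidy tci_window_fit
#' @export
tidy.tci_window_fit <- function(x, ...) {
  tibble(
    term = c("width", "center", "shape"),
    estimate = c(x$width, x$center, as.numeric(x$shape)),
    unit = c("s", "s", "")
  )
}

#' @describeIn fit_window One-row fit summary.
#' @method glance tci_window_fit
#' @export
glance.tci_window_fit <- function(x, ...) {
  tibble(
    neuron_id = x$neuron_id,
    width = x$width, center = x$center, shape = x$shape,
    loss = x$loss, n_points = x$n_points, n_durations = x$n_durations
  )
}
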