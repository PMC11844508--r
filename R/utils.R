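# internal helpers: seeding, interpolation, raised-cosine ramps

# Deterministic 31-bit integer seed from a string plus an integer stream
# offset. djb2-style accumulation in double precision (values stay < 2^53).
string_seed <- function(x, offset = 0L) {
  stopifnot(length(x) == 1L)
  bytes <- utf8ToInt(as.character(x))
  h <- 5381
  m <- 2147483647 # 2^31 - 1
  for (b in bytes) {
    h <- (h * 33 + b) %% m
  }
  as.integer((h + (as.numeric(offset) %% m) * 48271) %% m)
}

# run code with a local RNG state
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# linear interpolation on a uniform grid starting at x0 with step dt;
# queries outside the grid return `fill`. Vectorised, no approx() overhead.
interp_uniform <- function(y, x0, dt, xout, fill = 0) {
  pos <- (xout - x0) / dt
  i0 <- floor(pos)
  frac <- pos - i0
  n <- length(y)
  lo <- i0 + 1          # R index of left neighbour
  hi <- lo + 1
  ylo <- ifelse(lo >= 1 & lo <= n, y[pmin(pmax(lo, 1), n)], fill)
  yhi <- ifelse(hi >= 1 & hi <= n, y[pmin(pmax(hi, 1), n)], fill)
  ylo * (1 - frac) + yhi * frac
}

# raised-cosine (Hann) crossfade weight rising 0 -> 1 over [t0, t0 + ramp]
raised_cosine_up <- function(t, t0, ramp) {
  u <- (t - t0) / ramp
  u <- pmin(pmax(u, 0), 1)
  0.5 * (1 - cos(pi * u))
}

# boxcar over [0, duration] with raised-cosine transitions of total length
# `ramp` centred on each edge (weight 0.5 at the nominal boundary, matching
# the crossfade midpoint convention)
tapered_boxcar <- function(t, duration, ramp) {
  up <- raised_cosine_up(t, -ramp / 2, ramp)
  down <- 1 - raised_cosine_up(t, duration - ramp / 2, ramp)
  up * down
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
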