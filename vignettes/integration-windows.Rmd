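---
title: "Estimating neural integration windows from segment-shuffled sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating neural integration windows from segment-shuffled sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the design

A sensory neuron's *integration window* is the stretch of recent stimulus
history that can still change its response. `tciwin` estimates this window
from a segment-shuffling design: natural sounds are cut into segments of
several durations (e.g. 500 down to 31.25 ms, each tier obtained by
subdividing the tier above at its midpoint), and the segments are played in
two different pseudorandom orders. Any segment is therefore heard twice with
different *contexts* — different material immediately before and after it.
If the neuron's window fits inside the segment, there is a lag at which the
window sees only shared material and the response must be identical across
the two orders; if the window is longer than the segment, the surrounding
context leaks in and the responses decorrelate.

Consecutive segments are joined with a raised-cosine crossfade
(15.625 ms by default). We adopt the convention that a segment's nominal
onset is the midpoint of its leading crossfade, so each presented segment
carries half a ramp of extra material on each side and consecutive
presentations overlap by exactly one ramp.

## Cross-context correlation and noise ceiling

For one unit and one segment duration, binned responses (5 ms bins by
default) are organised as a matrix `M[i, tau, c, r]`: segment `i`, lag
`tau` from segment onset, context `c` in {1, 2}, stimulus repetition `r`.
The cross-context correlation (CCC) at lag `tau` is the Pearson correlation
across segments between the two contexts, averaged over all ordered pairs
of repetitions (`1/R^2` of the sum over pairs; equal repetition indices are
fine because they come from different contexts). The noise ceiling applies
the same correlation between distinct repetitions of the *same* context,
averaged over ordered pairs and then over the two contexts. It is the
highest CCC the unit's own reliability permits, and it is computed per
unit, duration and lag, so variations in response reliability are accounted
for. Columns with fewer than 3 complete segments or zero variance are
dropped from the averages rather than poisoning them.

Because shorter segments are embedded in longer ones, a segment can also
occur *inside* a presentation of its parent — its natural context. Pairs of
one direct (random-context) and one embedded (natural-context) occurrence
are pooled with random–random pairs by default; pairs of two embedded
occurrences are excluded because the two contexts would be identical.
Group-level summaries divide the median CCC over units by the median noise
ceiling, masking lags where the median ceiling falls below 0.05.

## The Gamma window model

The window is a Gamma density in lag, parametrized by

* **width** `w` — the smallest interval containing 75% of the window's
  mass (seconds; grid 1/128 to 0.5 s),
* **center** `c` — the window's median, i.e. the overall stimulus-to-window
  delay (seconds; grid 1 ms to 0.25 s),
* **shape** `beta` — 1 (exponential-like) to 5 (more Gaussian-like).

A baseline Gamma with shape `beta` and rate `beta` (unit mean) has width
`w_d` and center `c_d`; `c_d` comes from the inverse CDF and `w_d` from an
exhaustive scan of interval lower edges (CDF-based mass, tolerance 1e-6;
for `beta = 1` these are ln 2 and ln 4). The requested window is the
baseline scaled by `lambda = w / w_d` and shifted by
`delta = c - lambda * c_d`; `delta < 0` would be acausal and such parameter
combinations are excluded from fitting (tolerance: half a grid step). The
minimal causal center for a width is `(w / w_d) * c_d`.

The model predicts the CCC from overlaps. The overlap `s(tau)` of the
window with a segment is the convolution of the discretized window with a
boxcar spanning the segment, its edges tapered by the same raised-cosine
ramp as the stimulus crossfade. With the shared segment at lag 0 and
same-duration segments tiling the axis on both sides, the predicted CCC is

```
P(tau) = ceiling(tau) * s_shared(tau)^2 /
         (s_shared(tau)^2 + sum_n s_surround_n(tau)^2)
```

Fitting minimizes the unweighted sum of squared differences between the
measured CCC and `P` pooled over durations and defined lags, by exhaustive
search over the 100 x 100 x 5 grid. Exact ties break toward the smaller
width, then center, then shape. An option weights the error by the squared
ceiling, and another restricts the lag range; both default off because the
pooled unweighted loss is the simplest defensible choice. The log-spaced
center grid cannot start at zero, so it starts at 1 ms.

## Rate yoking

Stretching or compressing sounds (phase-vocoder style; emulated here by
time-scaling the latent feature traces) changes the information rate
without changing the content. A *time-yoked* window is fixed in absolute
time; a *rate-yoked* window scales with the stimulus. The rate-yoking index
is the octave difference between the windows fitted to stretched and
compressed sounds divided by the octave difference a fully rate-yoked
window would show: 0 means time-yoked, 1 means rate-yoked, and noise can
push it outside these bounds. When windows are measured at rate factors 0.5
and 2, a fully rate-yoked window differs by two octaves, so the pipeline
(`yoking_indices()`) normalizes by `log2(rho_stretched / rho_compressed)`;
`rate_yoking_index()` takes the rate ratio explicitly as `factor`.
Split-half reliability of the per-unit index (and of the rate-averaged
width) is assessed by Spearman correlation across units between fits on odd
and even repetitions, with a bootstrap-over-units two-sided p-value.

## Unit screening

Units enter the analysis only if their response timecourse is reliable: the
Pearson correlation between mean timecourses over odd and even repetitions,
concatenated across all sequences, must reach 0.1 (0.05 for sparse
populations) and be significant at p < 1e-5 under a permutation test. The
null permutes contiguous 100 ms blocks of one half against the intact other
half (1000 permutations) — permuting one half is our reading of an
ambiguous description, and is conservative in that the intact half keeps
its autocorrelation. A Gaussian is fitted to the null correlations so that
p-values far below 1/1000 remain measurable.

## The synthetic-data generator

Because the recordings behind this method are not bundled, the package
generates model neurons with *known* windows. Each source sound is
represented by a latent drive: a random Fourier series with 64 components
drawn uniformly from 1–50 Hz (unit variance, zero mean in expectation).
The series is a continuous function of content time, so stretched and
compressed versions are exact time dilations, and a segment embedded in its
parent carries exactly the content of its direct presentation. Sequences
are rendered with the same raised-cosine crossfades as the stimuli, so
context leakage at boundaries matches the experiment. A neuron filters the
drive with its (discretized) Gamma window, applies a static nonlinearity
(rectification by default, to exercise the method on a nonlinear system),
a gain (default 120 spikes/s per unit drive) and baseline (default
5 spikes/s), and emits Poisson spikes at a 2^-10 s resolution. A
rate-yoked neuron's effective window has width and center multiplied by the
stimulus rate factor; a time-yoked neuron's window is unchanged.

The default study (`study_spec()`) is desk-scale: 8 sources, 5 tiers
(500 to 31.25 ms), 8 repetitions, two groups of 10 neurons with
log-uniform widths of 15–60 ms and 40–150 ms, mimicking the primary /
non-primary contrast. What the generator does *not* emulate: spectrotemporal
tuning (the drive is one-dimensional), adaptation and other
history-dependent gain changes, across-trial nonstationarity (its noise
ceiling structure is purely Poisson), and correlated variability across
units. Passing tests therefore certify the estimation pipeline, not the
biology.

### What the overlap model assumes about the content

The prediction formula treats each segment's content as a coherent unit:
the variance of the shared-segment response component is the squared summed
overlap `s^2`. That is exact when content is fully correlated within the
span of the window (e.g. one level per segment) and only approximate for
band-limited time-varying content, whose correlation time under the flat
1–50 Hz spectrum is ~10–20 ms. With this generator the prediction deviates
from the empirical CCC by a systematic RMS that grows with window width —
for a rectifying neuron roughly 0.02 at 8 ms up to 0.06 at 62.5 ms, and
about 0.10 at 31 ms for a purely linear one (rectification adds slow
envelope components that behave more like coherent per-segment content,
so the field's typical nonlinear neurons sit closer to the model than the
linear idealization). The error concentrates at onset/offset transition
lags; a 2 ms near-delta window shows no deviation, and a fit to curves
generated by the model itself returns the exact grid point with zero
loss, so the implementation itself is consistent. No admissible spectrum
removes this: coherence long enough to make the formula exact for
30–150 ms windows would make 500 ms segments of the same statistics
mutually correlated, breaking the independence the correlation-across-
segments logic needs. The practical consequence is mild — the fitted width
absorbs most of it, with a residual bias of roughly -0.1 octave for
mid-range windows, well within the grid search's resolution and the
recovery tolerances used in the tests.

## Numerical choices

* Simulation and window-discretization step `2^-10 s` (~0.977 ms): every
  tier duration (500/2^k ms) is then an integer number of steps, which
  makes the periodic surround fold exact and lets noiseless responses to a
  shared segment agree bit-for-bit across orders (the basis of the exact
  context-invariance check). Designs with 200 ms segments use a 1 ms step
  for the same reason.
* Windows are discretized by cell-integrated mass (CDF differences), with
  the support truncated at a total tail mass of 1e-4 and renormalized, so
  every discretized window sums to exactly 1.
* Occurrence onsets snap to the nearest bin edge; reported lags are bin
  centers relative to the nominal onset, so the common sub-bin offset is
  carried in the lag values rather than lost.
* The fit grid is precomputed once per set of durations and lags
  (`build_fit_grid()`): the overlap ratio for all 50,000 parameter
  combinations is stored as a matrix, making each unit's fit two
  matrix-vector products. Surrounds are summed by folding `s^2` with
  period equal to the segment duration, which covers arbitrarily many
  flanking segments exactly.
* All randomness flows from explicit seeds through named substreams
  (design, features, spiking, permutations, bootstrap); rerunning any
  generator with the same seed is bit-reproducible.
* Problem sizes in the test-suite: unit tests run 2–24 sources; the
  oracle-equivalence check uses 512 sources so that finite-segment
  sampling noise (~1/sqrt(n) per lag) stays near 0.02 RMS; window
  recovery uses 24 sources (48+ segments per analysed tier) and 8
  repetitions; yoking recovery uses two populations of 6 neurons at rate
  factors 0.5 and 2.

## Known limitations

* The prediction formula's coherence approximation above.
* The pseudorandom order-B construction resamples (up to 1000 tries) until
  no segment keeps its order-A predecessor; for tiers with fewer than 3
  segments this is unsatisfiable and a warning is emitted.
* The bottom tier may not be shorter than the crossfade ramp (the ramps
  would collide); tiers shorter than two ramps are allowed with a warning,
  matching designs where the shortest segment equals the ramp.
* Window widths outside the fit grid (below ~7.8 ms or above 500 ms)
  cannot be recovered, and centers are only identified up to the grid's
  1 ms lower edge.
* Group comparisons (regions, layers) by mixed-effects modelling are out
  of scope; the package stops at per-unit fits and simple group medians.
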