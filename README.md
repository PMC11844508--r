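# tciwin

Estimation of neural **temporal integration windows** from responses to
segment-shuffled natural-sound sequences, for electrophysiologists and
computational neuroscientists who want to know *how much stimulus history*
a neuron's response depends on.

## The method

Natural sounds are cut into segments of several durations (each tier a
midpoint subdivision of the one above, e.g. 500 → 31.25 ms) and presented
in two pseudorandom orders joined by raised-cosine crossfades. Each segment
is then heard in two different *contexts*. Responses are binned (5 ms) and
organised per duration as `M[i, τ; c, r]` (segment × lag × context ×
repetition). The **cross-context correlation**

CCC(τ) = (1/R²) Σ_{r₁,r₂} corr( M[:, τ; 1, r₁], M[:, τ; 2, r₂] )

is compared with its **noise ceiling**, the same correlation between
repetitions of the identical context:

ceiling(τ) = ½ Σ_c [1/(R(R−1))] Σ_{r₁≠r₂} corr( M[:, τ; c, r₁], M[:, τ; c, r₂] )

If the neuron's window fits inside the segment there is a lag where
CCC = ceiling (context invariance); segments shorter than the window leave
the CCC below the ceiling. A **Gamma-shaped window** — parametrized by its
width (smallest interval holding 75% of the mass), center (median) and
shape — predicts the CCC via the relative squared overlap of the window
with the shared versus surrounding segments,

P(τ) = ceiling(τ) · s_shared(τ)² / (s_shared(τ)² + Σₙ s_surround,n(τ)²),

and is fitted by exhaustive grid search (100 log-spaced widths 1/128–0.5 s ×
100 log-spaced centers 1–250 ms × shapes 1–5, acausal combinations
excluded). A **rate-yoking index** — the octave difference between windows
fitted to stretched and compressed sounds, normalized by the octave span of
the information rates — distinguishes windows fixed in absolute time
(index 0) from windows yoked to the information rate (index 1).

Because the underlying recordings are not distributable, the package ships
a synthetic study generator (`study_spec()`, `generate_study()`): model
neurons with known Gamma windows, band-limited latent feature traces,
crossfaded sequences, Poisson spiking, and time- or rate-yoked behaviour,
so the whole pipeline is testable end to end against ground truth.

## Worked example

```r
library(tciwin)

# a small synthetic study: 8 sources, tiers 500..31.25 ms, 8 repetitions,
# 4 primary-like (15-60 ms) and 4 nonprimary-like (40-150 ms) neurons
spec <- study_spec(
  groups = tibble::tibble(
    group = c("primary", "nonprimary"), n = c(4L, 4L),
    width_lo = c(0.015, 0.040), width_hi = c(0.060, 0.150),
    yoking = "time_yoked"
  ),
  master_seed = 7
)
study <- generate_study(spec)
fits <- fit_study(study, durations = c(0.25, 0.125, 0.0625, 0.03125))
scores <- score_recovery(fits, study$truth)
recovery_summary(scores)
```

```
# A tibble: 1 × 5
      n n_missing median_error median_abs_error iqr_error
  <int>     <int>        <dbl>            <dbl>     <dbl>
1     8         0       -0.180            0.254     0.315
```

Eight of eight units pass the reliability screen (`n_missing = 0`) and the
fitted widths recover the generative ones to a median absolute error of
0.25 octaves (at this deliberately small scale of 8 sources; the larger
designs exercised in the test suite do better), with a slight narrow-ward bias of
-0.18 octaves, the expected signature of time-varying content inside the
fitted windows. Per-unit curves are easy to inspect:

```r
prof <- with(study, ccc_profiles(
  bin_response(spikes, 0.005), sequences[[1]], libraries[[1]],
  durations = c(0.25, 0.0625)
))
autoplot(dplyr::filter(prof, neuron_id == "primary_01"))
```

which shows the cross-context correlation rising to the noise ceiling
within each segment and collapsing at segment boundaries — earlier for the
short-window unit, later (or not at all at short durations) for long-window
units.

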