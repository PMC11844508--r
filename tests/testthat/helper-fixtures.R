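# Shared fixtures, memoized for the duration of the test run. Everything
# is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) {
    .fixtures[[name]] <- force(expr)
  }
  .fixtures[[name]]
}

# 2 sources x 3 tiers (400/200/100 ms), hand-enumerable
tiny_library <- function() {
  fixture("tiny_library", {
    build_segment_library(
      source_sounds(2, nominal_duration = 0.4),
      top_tier = 0.4, n_tiers = 3, ramp = 0.01
    )
  })
}

# noiseless linear pipeline: 24 sources, tiers 250/125/62.5 ms, 15 ms window
noiseless_pipeline <- function() {
  fixture("noiseless_pipeline", {
    lib <- build_segment_library(source_sounds(24), top_tier = 0.25, n_tiers = 3)
    seqs <- generate_sequences(lib, "per_duration", seed = 11)
    nrn <- neuron_spec("nl1",
      width = 0.015, shape = 2, nonlinearity = "identity",
      gain = 1, baseline_rate = 10, feature_seed = 5
    )
    sim <- simulate_response(nrn, seqs, lib, n_reps = 2, noise = "none")
    binned <- bin_response(sim, 0.005)
    profiles <- ccc_profiles(binned, seqs, lib)
    list(
      lib = lib, seqs = seqs, neuron = nrn, sim = sim,
      binned = binned, profiles = profiles
    )
  })
}

# hand-built binned container (no simulation)
fake_binned <- function(counts_by_row, bin_width = 0.005) {
  out <- counts_by_row
  attr(out, "bin_width") <- bin_width
  attr(out, "n_rejected") <- 0L
  class(out) <- c("tci_binned", class(tibble::tibble()))
  out
}
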