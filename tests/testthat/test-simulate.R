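test_that("a delta-like window with identity output reproduces the drive", {
  lib <- tiny_library()
  seqs <- suppressWarnings(generate_sequences(lib, "per_duration", seed = 2, tiers = 0.4))
  one <- dplyr::filter(seqs, order_label == "A")
  nrn <- neuron_spec("d1",
    width = 0.002, shape = 2, nonlinearity = "identity",
    gain = 1, baseline_rate = 10, feature_seed = 7
  )
  sim <- simulate_response(nrn, one, lib, noise = "none")
  tr <- render_sequence_trace(one, lib, feature_seed = 7)
  lag <- round(nrn$center / attr(sim, "dt")) # the window's own short latency
  keep <- which(sim$time_s > 0.02)
  expect_gt(cor(sim$rate_hz[keep], tr$value[keep - lag]), 0.99)
})

test_that("time-yoked windows ignore the stimulus rate; rate-yoked scale with it", {
  ty <- neuron_spec("t", width = 0.04, shape = 2, yoking = "time_yoked")
  ry <- neuron_spec("r", width = 0.04, shape = 2, yoking = "rate_yoked")
  w_t <- vapply(c(0.5, 1, 2), function(rho) {
    measure_window_stats(tciwin:::effective_window(ty, rho))$width
  }, numeric(1))
  expect_equal(w_t[1], w_t[2])
  expect_equal(w_t[2], w_t[3])
  w_r <- vapply(c(0.5, 2), function(rho) {
    measure_window_stats(tciwin:::effective_window(ry, rho))$width
  }, numeric(1))
  expect_equal(w_r[2] / w_r[1], 4, tolerance = 0.05) # two octaves
})

test_that("poisson spiking matches the underlying rate in the mean", {
  lib <- build_segment_library(source_sounds(2), top_tier = 0.5, n_tiers = 1)
  seqs <- suppressWarnings(generate_sequences(lib, "per_duration", seed = 3))
  one <- dplyr::filter(seqs, order_label == "A")
  nrn <- neuron_spec("p1", width = 0.03, shape = 2, gain = 80, baseline_rate = 10)
  rates <- simulate_response(nrn, one, lib, noise = "none")
  spk <- simulate_response(nrn, one, lib, n_reps = 200, noise = "poisson", sim_seed = 4)
  expected <- sum(rates$rate_hz) * attr(rates, "dt")
  observed <- nrow(spk) / 200
  expect_equal(observed, expected, tolerance = 0.03)
  # per-bin means track rate(t) * dt
  b <- bin_response(spk, 0.01, t_end = 1)
  mean_counts <- Reduce(`+`, b$counts) / nrow(b)
  rate_bin <- bin_response(rates, 0.01, t_end = 1)$counts[[1]]
  expect_gt(cor(mean_counts, rate_bin), 0.95)
})

test_that("spiking is reproducible given the seed and differs across reps", {
  lib <- tiny_library()
  seqs <- suppressWarnings(generate_sequences(lib, "per_duration", seed = 2, tiers = 0.4))
  nrn <- neuron_spec("p2", width = 0.03, shape = 2)
  s1 <- simulate_response(nrn, seqs, lib, n_reps = 2, sim_seed = 9)
  s2 <- simulate_response(nrn, seqs, lib, n_reps = 2, sim_seed = 9)
  expect_identical(s1, s2)
  r1 <- s1$spike_time_s[s1$repetition == 1 & s1$sequence_id == s1$sequence_id[1]]
  r2 <- s1$spike_time_s[s1$repetition == 2 & s1$sequence_id == s1$sequence_id[1]]
  expect_false(identical(r1, r2))
})

test_that("noiseless responses are identical across orders at contained lags", {
  fx <- noiseless_pipeline()
  prs <- enumerate_context_pairs(fx$seqs, fx$lib, 0.25, include_embedded = FALSE)
  b1 <- dplyr::filter(fx$binned, repetition == 1)
  attr(b1, "bin_width") <- 0.005
  m <- build_response_matrix(b1, prs)
  # window support ~185 ms: lags fully inside the 250 ms segment
  contained <- m$lags > 0.20 & m$lags < 0.24
  expect_true(any(contained))
  expect_equal(m$M[, contained, 1, 1], m$M[, contained, 2, 1], tolerance = 1e-12)
})
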