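test_that("the yoking index hits its analytic anchor values", {
  expect_equal(rate_yoking_index(0.100, 0.050, factor = 2), 1)
  expect_equal(rate_yoking_index(0.060, 0.060, factor = 2), 0)
  expect_equal(rate_yoking_index(0.040, 0.080, factor = 2), -1)
  # unit-invariant: ms vs s
  expect_equal(
    rate_yoking_index(100, 50, factor = 2),
    rate_yoking_index(0.1, 0.05, factor = 2)
  )
  # a 4x rate span normalizes a two-octave shift to 1
  expect_equal(rate_yoking_index(0.120, 0.030, factor = 4), 1)
  expect_error(rate_yoking_index(0, 0.05), "positive")
  expect_error(rate_yoking_index(0.1, 0.05, factor = 1), "exceed 1")
})

test_that("yoking_indices normalizes by the measured rate span", {
  fits <- tibble::tibble(
    neuron_id = rep(c("a", "b"), each = 2),
    rate_factor = rep(c(0.5, 2), 2),
    width = c(0.03, 0.12, 0.05, 0.05) # a: fully rate-yoked, b: time-yoked
  )
  idx <- yoking_indices(fits)
  expect_equal(idx$yoking_index[idx$neuron_id == "a"], 1)
  expect_equal(idx$yoking_index[idx$neuron_id == "b"], 0)
  expect_equal(idx$mean_width[idx$neuron_id == "b"], 0.05)
})

make_split_fits <- function(true_idx, base_width, noise_sd, seed) {
  n <- length(true_idx)
  withr::with_seed(seed, {
    purrr::map_dfr(1:2, function(sp) {
      purrr::map_dfr(seq_len(n), function(i) {
        w_c <- base_width[i] * 2^(-true_idx[i] / 2) # compressed (rho 0.5)
        w_s <- base_width[i] * 2^(+true_idx[i] / 2) # stretched (rho 2)
        tibble::tibble(
          neuron_id = sprintf("u%02d", i), split = sp,
          rate_factor = c(0.5, 2),
          width = c(w_c, w_s) * 2^rnorm(2, sd = noise_sd)
        )
      })
    })
  })
}

test_that("heterogeneous yoking and widths are reliable across splits at high SNR", {
  true_idx <- seq(0, 1, length.out = 20)
  widths <- withr::with_seed(8, exp(runif(20, log(0.02), log(0.1))))
  fits <- make_split_fits(true_idx, widths, noise_sd = 0.08, seed = 21)
  rel <- yoking_reliability(fits, n_boot = 300, seed = 3)
  expect_gt(rel$rho_yoking, 0.5)
  expect_lt(rel$p_yoking, 0.05)
  expect_gt(rel$rho_width, 0.5)
  expect_lt(rel$p_width, 0.05)
})

test_that("a time-yoked population shows no spurious yoking reliability", {
  n_sig <- 0L
  for (run in 1:12) {
    widths <- withr::with_seed(100 + run, exp(runif(15, log(0.02), log(0.1))))
    fits <- make_split_fits(rep(0, 15), widths, noise_sd = 0.15, seed = 200 + run)
    rel <- yoking_reliability(fits, n_boot = 200, seed = run)
    n_sig <- n_sig + (rel$p_yoking < 0.05 && rel$rho_yoking > 0)
  }
  expect_lte(n_sig, 2L) # calibrated: significant in <= ~10% of runs
})

test_that("reliability refuses fewer than 10 complete units", {
  fits <- make_split_fits(rep(0, 5), rep(0.05, 5), 0.1, 1)
  expect_error(yoking_reliability(fits), ">= 10")
})
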