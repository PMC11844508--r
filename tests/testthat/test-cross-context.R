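make_matrix_set <- function(M, duration = 0.1, bw = 0.005) {
  lags <- (seq_len(dim(M)[2]) - 1) * bw
  structure(
    list(
      M = M, lags = lags, duration = duration,
      pairs = NULL, bin_width = bw, neuron_id = "n1", n_reps = dim(M)[4]
    ),
    class = "tci_response_matrix"
  )
}

test_that("ccc is symmetric under context relabeling and affine rescaling", {
  M <- withr::with_seed(2, array(rnorm(30 * 8 * 2 * 3), dim = c(30, 8, 2, 3)))
  ms <- make_matrix_set(M)
  ccc <- cross_context_correlation(ms)
  swapped <- make_matrix_set(M[, , 2:1, , drop = FALSE])
  expect_equal(as.numeric(ccc), as.numeric(cross_context_correlation(swapped)))
  scaled <- make_matrix_set(3.7 * M + 11)
  expect_equal(as.numeric(ccc), as.numeric(cross_context_correlation(scaled)))
})

test_that("noiseless repetitions give a ceiling of one everywhere", {
  base <- withr::with_seed(3, array(rnorm(20 * 5 * 2), dim = c(20, 5, 2, 1)))
  M <- array(rep(base, 3), dim = c(20, 5, 2, 3)) # identical reps
  ceil <- noise_ceiling(make_matrix_set(M))
  expect_equal(ceil, rep(1, 5))
})

test_that("with two repetitions the ceiling equals the single pair correlation", {
  M <- withr::with_seed(4, array(rnorm(25 * 4 * 2 * 2), dim = c(25, 4, 2, 2)))
  ceil <- noise_ceiling(make_matrix_set(M))
  manual <- vapply(1:4, function(l) {
    mean(c(
      cor(M[, l, 1, 1], M[, l, 1, 2]),
      cor(M[, l, 2, 1], M[, l, 2, 2])
    ))
  }, numeric(1))
  expect_equal(ceil, manual)
})

test_that("a pure-noise unit has near-zero ceiling and ccc", {
  M <- withr::with_seed(5, array(rnorm(400 * 6 * 2 * 2), dim = c(400, 6, 2, 2)))
  ms <- make_matrix_set(M)
  expect_lt(mean(abs(noise_ceiling(ms))), 2 / sqrt(400))
  expect_lt(mean(abs(cross_context_correlation(ms))), 2 / sqrt(400))
})

test_that("zero-variance columns are dropped from the average, not poisoned", {
  M <- withr::with_seed(6, array(rnorm(10 * 2 * 2 * 2), dim = c(10, 2, 2, 2)))
  M[, 1, 1, 1] <- 5 # constant column in one (context, rep)
  ccc <- cross_context_correlation(make_matrix_set(M))
  expect_true(all(is.finite(ccc)))
  expect_gt(attr(ccc, "n_dropped")[1], 0)
})

test_that("noiseless linear unit: peak ccc is 1, onset ccc near 0, tracks ceiling", {
  fx <- noiseless_pipeline()
  prof <- fx$profiles
  support <- max(tciwin:::effective_window(fx$neuron, 1)$tau)
  for (d in unique(prof$duration)) {
    p <- prof[prof$duration == d, ]
    if (d > support + fx$lib$ramp) {
      # the window fits inside the segment: full context invariance
      expect_equal(max(p$ccc, na.rm = TRUE), 1, tolerance = 1e-10)
    } else {
      # segment shorter than the window: the ccc plateaus below the ceiling
      expect_lt(max(p$ccc, na.rm = TRUE), 1 - 1e-4)
      expect_gt(max(p$ccc, na.rm = TRUE), 0.8)
    }
    expect_equal(p$ceiling[!is.na(p$ceiling)], rep(1, sum(!is.na(p$ceiling))))
    onset <- which.min(abs(p$lag))
    expect_lt(abs(p$ccc[onset]), 0.45) # ~0 given 48-192 segments
  }
  # ccc never systematically exceeds the ceiling
  expect_true(all(prof$ccc <= prof$ceiling + 1e-9, na.rm = TRUE))
})

test_that("group normalization reduces to ccc/ceiling for a single unit", {
  fx <- noiseless_pipeline()
  norm <- group_normalized_ccc(fx$profiles)
  joined <- dplyr::left_join(
    norm, fx$profiles,
    by = c("duration", "lag")
  )
  ok <- !is.na(joined$normalized)
  expect_equal(joined$normalized[ok], (joined$ccc / joined$ceiling)[ok])
  expect_error(group_normalized_ccc(fx$profiles[0, ]), "empty")
})
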