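small_spec <- function(...) {
  study_spec(
    n_sources = 4L, n_tiers = 2L, n_reps = 4L,
    groups = tibble::tibble(
      group = "g", n = 2L, width_lo = 0.02, width_hi = 0.08,
      yoking = "time_yoked"
    ),
    master_seed = 5L, ...
  )
}

test_that("study generation is bit-reproducible for a fixed master seed", {
  s1 <- generate_study(small_spec())
  s2 <- generate_study(small_spec())
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$spikes, s2$spikes)
  s3 <- generate_study(study_spec(
    n_sources = 4L, n_tiers = 2L, n_reps = 4L,
    groups = tibble::tibble(
      group = "g", n = 2L, width_lo = 0.02, width_hi = 0.08,
      yoking = "time_yoked"
    ),
    master_seed = 6L
  ))
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("ground truth stays within the requested group ranges", {
  st <- generate_study(small_spec())
  expect_true(all(st$truth$width >= 0.02 & st$truth$width <= 0.08))
  expect_true(all(st$truth$center >= minimal_center(st$truth$width, st$truth$shape[1]) - 1e-12))
})

test_that("zero-gain units are screened out; driven units fitted", {
  spec <- study_spec(
    n_sources = 4L, n_tiers = 2L, n_reps = 4L, gain = 0, baseline_rate = 20,
    groups = tibble::tibble(
      group = "flat", n = 2L, width_lo = 0.02, width_hi = 0.08,
      yoking = "time_yoked"
    ),
    master_seed = 2L
  )
  st <- generate_study(spec)
  fits <- fit_study(st, grid = window_grid(n_width = 10, n_center = 10, shapes = 2))
  expect_equal(nrow(fits), 0L)
})

test_that("recovery scoring reports exact fits as zero error and keeps misses", {
  st <- generate_study(small_spec())
  fits <- st$truth %>%
    dplyr::transmute(neuron_id, rate_factor = 1, width, center,
      shape = shape, loss = 0, split = NA_integer_
    )
  sc <- score_recovery(fits, st$truth)
  expect_equal(sc$error_log2, rep(0, nrow(st$truth)))
  sc2 <- score_recovery(fits[-1, ], st$truth)
  expect_equal(sum(is.na(sc2$error_log2)), 1L)
  expect_equal(recovery_summary(sc2)$n_missing, 1L)
  expect_equal(recovery_summary(sc)$median_abs_error, 0)
})

test_that("rate-yoked ground truth scales the scored width with the rate", {
  truth <- tibble::tibble(
    neuron_id = "r1", group = "g", width = 0.04, center = 0.04,
    shape = 2L, yoking = "rate_yoked", nonlinearity = "rectify",
    gain = 100, baseline_rate = 5, feature_seed = 1L
  )
  fits <- tibble::tibble(
    neuron_id = "r1", rate_factor = c(0.5, 2),
    width = c(0.02, 0.08), center = 0.04, shape = 2L, loss = 0,
    split = NA_integer_
  )
  sc <- score_recovery(fits, truth)
  expect_equal(sc$error_log2, c(0, 0))
})

test_that("the full pipeline orders primary-like below nonprimary-like widths", {
  spec <- study_spec(
    n_sources = 6L, n_tiers = 3L, n_reps = 4L, gain = 180, baseline_rate = 2,
    groups = tibble::tibble(
      group = c("meg", "peg"), n = c(3L, 3L),
      width_lo = c(0.016, 0.07), width_hi = c(0.03, 0.14),
      yoking = "time_yoked"
    ),
    master_seed = 9L
  )
  st <- generate_study(spec)
  fits <- fit_study(st,
    grid = window_grid(n_width = 30, n_center = 20, shapes = 2),
    screen = FALSE
  )
  med <- tapply(fits$width, st$truth$group[match(fits$neuron_id, st$truth$neuron_id)], median)
  expect_lt(med[["meg"]], med[["peg"]])
})
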