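test_that("feature traces are deterministic and roughly standardized", {
  t1 <- segment_feature_trace("segA", 0.5, feature_seed = 3)
  t2 <- segment_feature_trace("segA", 0.5, feature_seed = 3)
  expect_identical(t1, t2)
  t3 <- segment_feature_trace("segA", 0.5, feature_seed = 4)
  expect_false(identical(t1$value, t3$value))
  expect_lt(abs(mean(t1$value)), 0.4)
  expect_gt(sd(t1$value), 0.5)
  expect_lt(sd(t1$value), 1.6)
})

test_that("rate-scaled traces are exact time dilations of the original", {
  dt <- 2^-10
  t1 <- segment_feature_trace("segA", 0.25, rate_factor = 1, feature_seed = 9, dt = dt)
  t2 <- segment_feature_trace("segA", 0.5, rate_factor = 2, feature_seed = 9, dt = dt)
  # every second sample of the stretched trace revisits the original grid
  expect_equal(t2$value[seq(1, nrow(t2), by = 2)], t1$value, tolerance = 1e-12)
})

test_that("traces of distinct segments are approximately uncorrelated", {
  tt <- seq_len(500)
  rs <- vapply(1:30, function(i) {
    a <- segment_feature_trace(sprintf("segA%02d", i), 0.5, feature_seed = i, dt = 0.001)
    b <- segment_feature_trace(sprintf("segB%02d", i), 0.5, feature_seed = i + 100, dt = 0.001)
    cor(a$value, b$value)
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.2)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("a segment's content matches its slice of the source", {
  # the same continuous source function backs parent and child segments
  child <- segment_feature_trace("c", 0.2,
    source_id = "srcX", onset_in_source = 0.2,
    feature_seed = 2, dt = 0.001
  )
  parent <- segment_feature_trace("p", 0.4,
    source_id = "srcX", onset_in_source = 0,
    feature_seed = 2, dt = 0.001
  )
  expect_equal(child$value, parent$value[parent$time >= 0.2 - 1e-12], tolerance = 1e-9)
})

test_that("rendered sequences equal the segment trace away from crossfades", {
  # binary-grid design: onsets land exactly on the simulation grid
  lib <- build_segment_library(source_sounds(4), top_tier = 0.5, n_tiers = 1)
  seqs <- generate_sequences(lib, "per_duration", seed = 2)
  one <- seqs[seqs$sequence_id == seqs$sequence_id[1], ]
  tr <- render_sequence_trace(one, lib, feature_seed = 7)
  ent <- one[2, ] # an interior segment
  seg <- lib$segments[lib$segments$segment_id == ent$segment_id, ]
  sel <- which(tr$time > ent$onset + lib$ramp / 2 &
    tr$time < ent$onset + ent$tier_duration - lib$ramp / 2)
  direct <- segment_feature_trace(seg$segment_id, ent$tier_duration,
    source_id = seg$source_id, onset_in_source = seg$onset_in_source,
    feature_seed = 7
  )
  offset <- round((tr$time[sel] - ent$onset) * 2^10) + 1L
  expect_equal(tr$value[sel], direct$value[offset], tolerance = 1e-9)
})
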