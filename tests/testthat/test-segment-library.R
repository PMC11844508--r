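test_that("midpoint subdivision yields the full tier hierarchy and counts", {
  lib <- suppressWarnings(
    build_segment_library(source_sounds(24), top_tier = 0.5, n_tiers = 6)
  )
  expect_equal(lib$tiers, 0.5 / 2^(0:5))
  counts <- table(factor(lib$segments$tier_duration, levels = lib$tiers))
  expect_equal(as.integer(counts), c(24L, 48L, 96L, 192L, 384L, 768L))
  expect_equal(
    lib$segments$presented_duration,
    lib$segments$tier_duration + lib$ramp
  )
})

test_that("a single source with one tier has one segment and no children", {
  lib <- build_segment_library(source_sounds(1), top_tier = 0.5, n_tiers = 1)
  expect_equal(nrow(lib$segments), 1L)
  expect_true(is.na(lib$segments$parent_id))
})

test_that("two sources over three tiers tile their parents exactly", {
  lib <- tiny_library()
  segs <- lib$segments
  expect_equal(nrow(segs), 14L) # 2 + 4 + 8
  t2 <- segs[abs(segs$tier_duration - 0.2) < 1e-12 & segs$source_id == "src01", ]
  expect_equal(sort(t2$onset_in_source), c(0, 0.2))
  t3 <- segs[abs(segs$tier_duration - 0.1) < 1e-12 & segs$source_id == "src01", ]
  expect_equal(sort(t3$onset_in_source), c(0, 0.1, 0.2, 0.3))
  # every parent is tiled by exactly two children at offsets {0, d/2}
  parents <- segs[!is.na(segs$parent_id), ]
  by_parent <- split(parents, parents$parent_id)
  for (ch in by_parent) {
    expect_equal(nrow(ch), 2L)
    pd <- segs$tier_duration[match(ch$parent_id[1], segs$segment_id)]
    po <- segs$onset_in_source[match(ch$parent_id[1], segs$segment_id)]
    expect_equal(sum(ch$tier_duration), pd)
    expect_equal(sort(ch$onset_in_source - po), c(0, pd / 2))
  }
})

test_that("designs whose tiers collide with the crossfade are rejected", {
  expect_error(
    build_segment_library(source_sounds(1, nominal_duration = 0.02),
      top_tier = 0.02, n_tiers = 2, ramp = 0.015
    ),
    "invalid design"
  )
  expect_warning(
    build_segment_library(source_sounds(1, nominal_duration = 0.06),
      top_tier = 0.06, n_tiers = 2, ramp = 0.02
    ),
    "crossfade"
  )
  expect_error(
    build_segment_library(source_sounds(2, nominal_duration = 0.3), top_tier = 0.4),
    "integer multiple"
  )
})

test_that("tiling conservation holds across randomized designs", {
  for (cfg in list(c(3, 4), c(5, 2), c(1, 5))) {
    lib <- suppressWarnings(build_segment_library(
      source_sounds(cfg[1]),
      top_tier = 0.5, n_tiers = cfg[2]
    ))
    segs <- lib$segments
    kids <- segs[!is.na(segs$parent_id), ]
    sums <- tapply(kids$tier_duration, kids$parent_id, sum)
    pd <- segs$tier_duration[match(names(sums), segs$segment_id)]
    expect_equal(as.numeric(sums), pd)
  }
})
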