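test_that("both orders are permutations with no shared predecessor bigrams", {
  lib <- tiny_library()
  seqs <- generate_sequences(lib, "interleaved", seed = 7)
  a <- seqs$segment_id[seqs$order_label == "A"]
  b <- seqs$segment_id[seqs$order_label == "B"]
  expect_setequal(a, lib$segments$segment_id)
  expect_setequal(b, lib$segments$segment_id)
  big <- function(x) paste(c("^", x[-length(x)]), x)
  expect_length(intersect(big(a), big(b)), 0L)
})

test_that("sequence generation is deterministic given the seed", {
  lib <- tiny_library()
  s1 <- suppressWarnings(generate_sequences(lib, "per_duration", seed = 42))
  s2 <- suppressWarnings(generate_sequences(lib, "per_duration", seed = 42))
  expect_identical(s1, s2)
  s3 <- suppressWarnings(generate_sequences(lib, "per_duration", seed = 43))
  expect_false(identical(s1$segment_id, s3$segment_id))
})

test_that("onsets advance by the tier duration and overlap by the ramp", {
  lib <- tiny_library()
  seqs <- suppressWarnings(generate_sequences(lib, "per_duration", seed = 1))
  for (sid in unique(seqs$sequence_id)) {
    ent <- seqs[seqs$sequence_id == sid, ]
    expect_equal(ent$onset[1], lib$ramp / 2)
    expect_equal(diff(ent$onset), head(ent$tier_duration, -1))
    # material of consecutive segments overlaps by exactly the ramp
    mat_end <- ent$onset + ent$tier_duration + lib$ramp / 2
    mat_start <- ent$onset - lib$ramp / 2
    expect_equal(mat_end[-nrow(ent)] - mat_start[-1], rep(lib$ramp, nrow(ent) - 1))
  }
  # total duration: sum of presented durations minus overlaps
  durs <- sequence_durations(seqs)
  ent <- seqs[seqs$sequence_id == durs$sequence_id[1], ]
  expect_equal(
    durs$duration[1],
    sum(ent$tier_duration + lib$ramp) - (nrow(ent) - 1) * lib$ramp
  )
})

test_that("a two-segment tier warns that predecessor diversity may fail", {
  lib <- build_segment_library(source_sounds(1, nominal_duration = 0.4),
    top_tier = 0.4, n_tiers = 2, ramp = 0.01
  )
  expect_warning(
    generate_sequences(lib, "per_duration", seed = 1, tiers = 0.2),
    "predecessor"
  )
})

test_that("random-random context pairs are one per segment without embedding", {
  lib <- tiny_library()
  seqs <- suppressWarnings(generate_sequences(lib, "per_duration", seed = 5))
  prs <- enumerate_context_pairs(seqs, lib, 0.2, include_embedded = FALSE)
  expect_equal(nrow(prs), 4L)
  expect_true(all(prs$context_type == "random_random"))
  expect_error(enumerate_context_pairs(seqs, lib, 0.3), "not a tier")
})

test_that("embedded occurrences form natural-random pairs at the right onset", {
  lib <- tiny_library()
  seqs <- suppressWarnings(generate_sequences(lib, "per_duration", seed = 5))
  prs <- enumerate_context_pairs(seqs, lib, 0.2, include_embedded = TRUE)
  # per segment: 1 random_random + 2 natural_random (embedded in the 400 ms
  # parent of either order vs direct in the other)
  expect_equal(sum(prs$context_type == "random_random"), 4L)
  expect_equal(sum(prs$context_type == "natural_random"), 8L)
  expect_true(all(!(prs$embedded_1 & prs$embedded_2)))
  nat <- prs[prs$context_type == "natural_random" & prs$embedded_1, ][1, ]
  seg <- lib$segments[lib$segments$segment_id == nat$segment_id, ]
  parent <- lib$segments[lib$segments$segment_id == seg$parent_id, ]
  parent_entry <- seqs[seqs$segment_id == parent$segment_id &
    seqs$sequence_id == nat$seq_1, ]
  expect_equal(
    nat$onset_1,
    parent_entry$onset + (seg$onset_in_source - parent$onset_in_source)
  )
})
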