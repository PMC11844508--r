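#' Describe a set of source sounds
#'
#' Convenience constructor for the source-sound table consumed by
#' [build_segment_library()]. Each source is a nominally 500 ms natural-sound
#' excerpt (or a stretched/compressed version of one).
#'
#' @param n Number of sources.
#' @param categories Character vector recycled across sources; one of
#'   `"speech"`, `"ferret_vocalization"`, `"music"`, `"other"`.
#' @param nominal_duration Duration of each source in seconds at its own
#'   rate (a rate-2 stretched 500 ms sound is nominally 1 s long).
#' @param rate_factor Information-rate factor: 1 = original, 2 = stretched
#'   (twice as long, half the rate), 0.5 = compressed.
#' @return A tibble with columns `sound_id`, `category`, `nominal_duration`,
#'   `rate_factor`.
#' @examples
#' source_sounds(4)
#' @export
source_sounds <- function(n, categories = c("speech", "ferret_vocalization", "music"),
                          nominal_duration = 0.5, rate_factor = 1) {
  stopifnot(n >= 1, nominal_duration > 0, rate_factor > 0)
  categories <- match.arg(categories,
    c("speech", "ferret_vocalization", "music", "other"),
    several.ok = TRUE
  )
  tibble(
    sound_id = sprintf("src%02d", seq_len(n)),
    category = rep_len(categories, n),
    nominal_duration = nominal_duration,
    rate_factor = rate_factor
  )
}

fmt_ms <- function(x) {
  formatC(x * 1000, format = "fg", digits = 10)
}

seg_id <- function(source_id, tier, onset) {
  sprintf("%s_d%s_o%s", source_id, fmt_ms(tier), fmt_ms(onset))
}

#' Build a segment library by midpoint subdivision
#'
#' Cuts each source sound into top-tier segments and recursively subdivides
#' each tier at its midpoint, so a parent of duration d has exactly two
#' children of duration d/2 at offsets 0 and d/2. Presented segments carry
#' an extra crossfade ramp (half on each side), so their physical duration
#' is `tier + ramp`.
#'
#' @param sources A tibble as returned by [source_sounds()] (columns
#'   `sound_id`, `category`, `nominal_duration`, `rate_factor`), or a single
#'   integer, shorthand for `source_sounds(n)`.
#' @param top_tier Duration in seconds of the longest segment tier.
#'   `nominal_duration` must be an integer multiple of it.
#' @param n_tiers Number of tiers; tier k has duration `top_tier / 2^(k-1)`.
#' @param ramp Crossfade ramp duration in seconds (raised cosine).
#' @return A `tci_segment_library`: list with elements `sources`, `segments`
#'   (tibble: `segment_id`, `source_id`, `tier_duration`, `onset_in_source`,
#'   `parent_id`, `presented_duration`), `tiers` (descending durations),
#'   `ramp`, `top_tier`.
#' @examples
#' lib <- build_segment_library(source_sounds(2, nominal_duration = 0.4),
#'   top_tier = 0.4, n_tiers = 3
#' )
#' nrow(lib$segments) # 2 + 4 + 8
#' @export
build_segment_library <- function(sources, top_tier = 0.5, n_tiers = 5,
                                  ramp = DEFAULT_RAMP) {
  if (is.numeric(sources) && length(sources) == 1L) {
    sources <- source_sounds(sources)
  }
  stopifnot(
    is.data.frame(sources), nrow(sources) >= 1,
    all(c("sound_id", "nominal_duration", "rate_factor") %in% names(sources)),
    is_scalar_number(top_tier), top_tier > 0,
    n_tiers >= 1, ramp >= 0
  )
  if (any(sources$nominal_duration <= 0) || any(sources$rate_factor <= 0)) {
    abort("source durations and rate factors must be positive")
  }
  n_top <- sources$nominal_duration / top_tier
  if (any(abs(n_top - round(n_top)) > 1e-9) || any(round(n_top) < 1)) {
    abort("each `nominal_duration` must be a positive integer multiple of `top_tier`")
  }
  tiers <- top_tier / 2^(seq_len(n_tiers) - 1)
  if (min(tiers) < ramp - 1e-12) {
    abort(sprintf(
      "invalid design: bottom tier (%.4g s) is shorter than the crossfade ramp (%.4g s)",
      min(tiers), ramp
    ))
  }
  if (min(tiers) < 2 * ramp - 1e-12) {
    warn(sprintf(
      "bottom tier (%.4g s) is shorter than twice the crossfade ramp; most of those segments is crossfade material",
      min(tiers)
    ))
  }

  segs <- purrr::map_dfr(seq_len(nrow(sources)), function(i) {
    src <- sources[i, ]
    purrr::map_dfr(seq_along(tiers), function(k) {
      d <- tiers[k]
      onsets <- seq(0, src$nominal_duration - d + 1e-12, by = d)
      parent <- if (k == 1L) {
        NA_character_
      } else {
        pd <- tiers[k - 1L]
        seg_id(src$sound_id, pd, floor(onsets / pd + 1e-9) * pd)
      }
      tibble(
        segment_id = seg_id(src$sound_id, d, onsets),
        source_id = src$sound_id,
        tier_duration = d,
        onset_in_source = onsets,
        parent_id = parent,
        presented_duration = d + ramp
      )
    })
  })

  structure(
    list(
      sources = as_tibble(sources),
      segments = segs,
      tiers = tiers,
      ramp = ramp,
      top_tier = top_tier
    ),
    class = "tci_segment_library"
  )
}

#' @export
print.tci_segment_library <- function(x, ...) {
  cat(sprintf(
    "<tci_segment_library> %d sources, %d tiers (%s ms), %d segments, ramp %.4g ms\n",
    nrow(x$sources), length(x$tiers),
    paste(fmt_ms(x$tiers), collapse = "/"),
    nrow(x$segments), x$ramp * 1000
  ))
  invisible(x)
}

# segments of one tier, matching by duration with tolerance
tier_segments <- function(library, duration) {
  k <- which(abs(library$tiers - duration) < 1e-9)
  if (length(k) != 1L) {
    abort(sprintf("duration %.6g s is not a tier of this library", duration))
  }
  dplyr::filter(library$segments, abs(.data$tier_duration - library$tiers[k]) < 1e-12)
}

# ancestor chain (parent, grandparent, ...) of a segment id
ancestor_ids <- function(library, segment_id) {
  segs <- library$segments
  out <- character(0)
  cur <- segs$parent_id[match(segment_id, segs$segment_id)]
  while (length(cur) == 1 && !is.na(cur)) {
    out <- c(out, cur)
    cur <- segs$parent_id[match(cur, segs$segment_id)]
  }
  out
}
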