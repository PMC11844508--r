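#' Generate pseudorandom presentation sequences
#'
#' Produces two pseudorandom orders (A and B) of the library's segments,
#' either one pair of sequences per tier (`per_duration`) or a single pair
#' interleaving every tier (`interleaved`). Consecutive segments overlap by
#' exactly the crossfade ramp; the nominal onset of a segment is the
#' midpoint of its leading ramp, so the first onset is `ramp/2` and onset
#' k+1 = onset k + tier k.
#'
#' Order B is resampled (up to `max_tries` seeded attempts) until no segment
#' keeps the predecessor it had in order A; for sequences of fewer than
#' three segments this constraint may be unsatisfiable and a warning is
#' emitted.
#'
#' @param library A [build_segment_library()] result.
#' @param mode `"per_duration"` (one sequence pair per tier) or
#'   `"interleaved"` (all tiers and categories shuffled jointly).
#' @param seed Integer seed; the same seed reproduces the sequences exactly.
#' @param tiers Durations to include (default: all library tiers).
#' @param n_repetitions Number of repetitions each sequence is presented.
#' @param per_category If `TRUE`, interleaved orders are shuffled within
#'   category blocks rather than jointly (default joint shuffling).
#' @param max_tries Resampling budget for the predecessor-diversity rule.
#' @return A `tci_sequences` tibble with columns `sequence_id`,
#'   `order_label`, `mode`, `tier_duration`, `position`, `segment_id`,
#'   `onset`, `n_repetitions`, and attributes `seed` and `ramp`.
#' @examples
#' lib <- build_segment_library(2, top_tier = 0.4, n_tiers = 2, ramp = 0.01)
#' generate_sequences(lib, "per_duration", seed = 7)
#' @export
generate_sequences <- function(library, mode = c("per_duration", "interleaved"),
                               seed = 1L, tiers = NULL, n_repetitions = 1L,
                               per_category = FALSE, max_tries = 1000L) {
  stopifnot(inherits(library, "tci_segment_library"))
  mode <- match.arg(mode)
  tiers <- tiers %||% library$tiers
  if (!all(vapply(tiers, function(d) any(abs(library$tiers - d) < 1e-9), logical(1)))) {
    abort("`tiers` must be a subset of the library tiers")
  }
  ramp <- library$ramp

  make_orders <- function(seg_tbl, local_seed) {
    ids <- seg_tbl$segment_id
    n <- length(ids)
    shuffle <- function(s) {
      if (!per_category || !"category" %in% names(seg_tbl)) {
        with_seed(s, sample(ids))
      } else {
        # shuffle within category, then shuffle the category blocks
        cat_of <- library$sources$category[match(seg_tbl$source_id, library$sources$sound_id)]
        with_seed(s, {
          parts <- split(ids, cat_of)
          unlist(lapply(parts[sample(names(parts))], sample), use.names = FALSE)
        })
      }
    }
    a <- shuffle(local_seed)
    if (n < 3L) {
      warn(sprintf(
        "sequence with %d segment(s): predecessor-diversity rule may be unsatisfiable",
        n
      ))
    }
    b <- NULL
    for (try in seq_len(max_tries)) {
      cand <- shuffle(local_seed + try)
      if (n < 3L || shared_predecessors(a, cand) == 0L) {
        b <- cand
        break
      }
    }
    if (is.null(b)) {
      warn("predecessor-diversity rule not satisfied within `max_tries`; using best effort")
      b <- cand
    }
    list(A = a, B = b)
  }

  entry_rows <- function(ids, seq_id, label, tier_na) {
    durs <- library$segments$tier_duration[match(ids, library$segments$segment_id)]
    onsets <- ramp / 2 + cumsum(c(0, durs[-length(durs)]))
    tibble(
      sequence_id = seq_id,
      order_label = label,
      mode = mode,
      tier_duration = if (is.na(tier_na)) durs else tier_na,
      position = seq_along(ids),
      segment_id = ids,
      onset = onsets,
      n_repetitions = as.integer(n_repetitions)
    )
  }

  out <- if (mode == "per_duration") {
    purrr::map_dfr(seq_along(tiers), function(k) {
      d <- tiers[k]
      segs <- tier_segments(library, d)
      ords <- make_orders(segs, string_seed(sprintf("d%s", fmt_ms(d)), seed))
      bind_rows(
        entry_rows(ords$A, sprintf("seq_d%s_A", fmt_ms(d)), "A", d),
        entry_rows(ords$B, sprintf("seq_d%s_B", fmt_ms(d)), "B", d)
      )
    })
  } else {
    segs <- dplyr::filter(
      library$segments,
      vapply(.data$tier_duration, function(d) any(abs(tiers - d) < 1e-9), logical(1))
    )
    ords <- make_orders(segs, string_seed("interleaved", seed))
    bind_rows(
      entry_rows(ords$A, "seq_all_A", "A", NA_real_),
      entry_rows(ords$B, "seq_all_B", "B", NA_real_)
    )
  }

  attr(out, "seed") <- as.integer(seed)
  attr(out, "ramp") <- ramp
  class(out) <- c("tci_sequences", class(tibble()))
  out
}

# number of segments whose predecessor (with a virtual start marker) is the
# same in both orders
shared_predecessors <- function(a, b) {
  pred_a <- setNames(c("^start", a[-length(a)]), a)
  pred_b <- setNames(c("^start", b[-length(b)]), b)
  sum(pred_a[a] == pred_b[a])
}

#' Total duration of each sequence
#'
#' Final material offset: sum of presented durations minus the crossfade
#' overlaps, i.e. sum(tiers) + ramp.
#'
#' @param sequences A `tci_sequences` tibble.
#' @return Tibble with `sequence_id` and `duration`.
#' @export
sequence_durations <- function(sequences) {
  ramp <- attr(sequences, "ramp")
  sequences %>%
    group_by(.data$sequence_id) %>%
    summarise(
      duration = max(.data$onset + .data$tier_duration) + ramp / 2,
      .groups = "drop"
    )
}

#' Enumerate shared-segment context pairs
#'
#' Lists every pair of occurrences of each segment of the requested duration
#' across the two presentation orders. Direct presentations in both orders
#' give `random_random` pairs (unrelated surroundings in both). When
#' `include_embedded` is `TRUE`, occurrences of the segment inside a
#' presentation of one of its ancestors (at the ancestor onset plus the
#' segment's offset within it) are also used; a pair of one direct and one
#' embedded occurrence is tagged `natural_random` (the embedded occurrence
#' keeps its original temporal surroundings). Pairs of two embedded
#' occurrences are excluded: both contexts are the natural one, so the
#' comparison is undefined.
#'
#' @param sequences A `tci_sequences` tibble.
#' @param library The segment library the sequences were drawn from.
#' @param duration Segment duration (must be a library tier).
#' @param include_embedded Include natural-context (embedded) occurrences.
#' @return Tibble with columns `segment_id`, `duration`, `seq_1`, `onset_1`,
#'   `embedded_1`, `seq_2`, `onset_2`, `embedded_2`, `context_type`.
#' @export
enumerate_context_pairs <- function(sequences, library, duration,
                                    include_embedded = TRUE) {
  stopifnot(inherits(library, "tci_segment_library"))
  segs <- tier_segments(library, duration)
  all_segs <- library$segments

  occurrences <- function(label) {
    ent <- dplyr::filter(sequences, .data$order_label == label)
    direct <- ent %>%
      dplyr::filter(.data$segment_id %in% segs$segment_id) %>%
      dplyr::transmute(
        segment_id = .data$segment_id,
        sequence_id = .data$sequence_id,
        onset = .data$onset,
        embedded = FALSE
      )
    if (!include_embedded) {
      return(direct)
    }
    emb <- purrr::map_dfr(seq_len(nrow(segs)), function(i) {
      s <- segs[i, ]
      anc <- ancestor_ids(library, s$segment_id)
      if (length(anc) == 0) {
        return(NULL)
      }
      anc_tbl <- all_segs[match(anc, all_segs$segment_id), ]
      hits <- ent %>% dplyr::filter(.data$segment_id %in% anc)
      if (nrow(hits) == 0) {
        return(NULL)
      }
      off <- s$onset_in_source -
        anc_tbl$onset_in_source[match(hits$segment_id, anc_tbl$segment_id)]
      tibble(
        segment_id = s$segment_id,
        sequence_id = hits$sequence_id,
        onset = hits$onset + off,
        embedded = TRUE
      )
    })
    bind_rows(direct, emb)
  }

  occ_a <- occurrences("A")
  occ_b <- occurrences("B")

  pairs <- dplyr::inner_join(
    occ_a, occ_b,
    by = "segment_id", suffix = c("_1", "_2"),
    relationship = "many-to-many"
  ) %>%
    dplyr::filter(!(.data$embedded_1 & .data$embedded_2)) %>%
    dplyr::transmute(
      segment_id = .data$segment_id,
      duration = duration,
      seq_1 = .data$sequence_id_1,
      onset_1 = .data$onset_1,
      embedded_1 = .data$embedded_1,
      seq_2 = .data$sequence_id_2,
      onset_2 = .data$onset_2,
      embedded_2 = .data$embedded_2,
      context_type = ifelse(.data$embedded_1 | .data$embedded_2,
        "natural_random", "random_random"
      )
    ) %>%
    arrange(.data$segment_id, .data$context_type)
  pairs
}
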