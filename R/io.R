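# File-format plumbing: JSON manifests for the stimulus design, TSV spike
# tables, YAML run configuration. Synthetic and recorded data travel
# through the same formats.

#' Write / read a segment library as JSON
#'
#' @param library A `tci_segment_library`.
#' @param path File path.
#' @return `read_segment_library()` returns the library; the writer
#'   returns `path` invisibly.
#' @export
write_segment_library <- function(library, path) {
  stopifnot(inherits(library, "tci_segment_library"))
  jsonlite::write_json(
    list(
      sources = library$sources,
      segments = library$segments,
      tiers = library$tiers,
      ramp = library$ramp,
      top_tier = library$top_tier
    ),
    path,
    digits = NA, auto_unbox = TRUE, na = "null"
  )
  invisible(path)
}

#' @rdname write_segment_library
#' @export
read_segment_library <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- as_tibble(x$segments)
  segs$parent_id <- as.character(segs$parent_id)
  structure(
    list(
      sources = as_tibble(x$sources),
      segments = segs,
      tiers = as.numeric(x$tiers),
      ramp = x$ramp,
      top_tier = x$top_tier
    ),
    class = "tci_segment_library"
  )
}

#' Write / read sequence manifests as JSON
#'
#' One manifest object per sequence: `sequence_id`, `order_label`,
#' `mode`, `seed`, `ramp`, `n_repetitions`, and the ordered entries
#' (`segment_id`, `onset` at microsecond precision).
#'
#' @param sequences A `tci_sequences` tibble.
#' @param path File path.
#' @export
write_sequence_manifest <- function(sequences, path) {
  seqs <- lapply(unique(sequences$sequence_id), function(sid) {
    ent <- dplyr::filter(sequences, .data$sequence_id == sid)
    list(
      sequence_id = sid,
      order_label = ent$order_label[1],
      mode = ent$mode[1],
      seed = attr(sequences, "seed"),
      ramp = attr(sequences, "ramp"),
      n_repetitions = ent$n_repetitions[1],
      entries = data.frame(
        segment_id = ent$segment_id,
        onset = round(ent$onset * 1e6) / 1e6
      )
    )
  })
  jsonlite::write_json(seqs, path, digits = 10, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sequence_manifest
#' @export
read_sequence_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- purrr::map_dfr(seq_len(nrow(x)), function(i) {
    ent <- x$entries[[i]]
    tibble(
      sequence_id = x$sequence_id[i],
      order_label = x$order_label[i],
      mode = x$mode[i],
      tier_duration = NA_real_,
      position = seq_len(nrow(ent)),
      segment_id = ent$segment_id,
      onset = ent$onset,
      n_repetitions = as.integer(x$n_repetitions[i])
    )
  })
  attr(out, "seed") <- as.integer(x$seed[1])
  attr(out, "ramp") <- x$ramp[1]
  class(out) <- c("tci_sequences", class(tibble()))
  out
}

#' Write / read spike event tables as TSV
#'
#' Columns: `neuron_id`, `sequence_id`, `repetition`, `spike_time_s`
#' (plus any extra columns, e.g. `rate_factor`).
#'
#' @param events Spike event tibble.
#' @param path File path.
#' @export
write_spike_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  attr(out, "kind") <- "spikes"
  out
}

#' Analysis run configuration
#'
#' Bundles the tunable analysis parameters (bin width, lag range,
#' screening threshold and permutation count, fit-grid spec, context-pair
#' pooling, seed) into a serializable object whose YAML round-trip is
#' exact and whose hash can be embedded in derived artifacts.
#'
#' @param bin_width,lag_pre,lag_post Binning and lag window (seconds;
#'   lags run from `-lag_pre` to `duration + lag_post`).
#' @param threshold,n_perm,block Reliability screen parameters.
#' @param include_embedded Pool natural-context pairs.
#' @param n_width,n_center,shapes Fit-grid controls, see [window_grid()].
#' @param seed Master seed.
#' @return A `tci_run_config` list.
#' @export
run_config <- function(bin_width = 0.005, lag_pre = 0.1, lag_post = 0.25,
                       threshold = 0.1, n_perm = 1000L, block = 0.1,
                       include_embedded = TRUE,
                       n_width = 100L, n_center = 100L, shapes = 1:5,
                       seed = 1L) {
  structure(
    list(
      bin_width = bin_width, lag_pre = lag_pre, lag_post = lag_post,
      threshold = threshold, n_perm = as.integer(n_perm), block = block,
      include_embedded = include_embedded,
      n_width = as.integer(n_width), n_center = as.integer(n_center),
      shapes = as.integer(shapes), seed = as.integer(seed)
    ),
    class = "tci_run_config"
  )
}

#' @rdname run_config
#' @param config A `tci_run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "tci_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  # hash the canonical YAML text so equal configurations hash equally
  # regardless of internal vector representation
  rlang::hash(yaml::as.yaml(unclass(config)))
}
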