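#' Pipeline configuration
#'
#' Collects every tunable parameter of the design pipeline with its default.
#' Defaults: 20 nt primers (the conventional primer length; for
#' adjacent-probe use a 20-mer splits into two 10-mers), minimum primer group
#' size 1, minimum sequence group size 2 (primers private to one sequence are
#' rarely useful for multiplexing; set 1 to force full coverage of small
#' inputs), 4 cumulative-coverage decimals, GC filters off.
#'
#' @param primer_length Candidate length k in bases, integer >= 2.
#' @param min_primer_group_size,min_sequence_group_size Cluster size
#'   cut-offs, integers >= 1.
#' @param decimals Cumulative-coverage rounding precision, integer >= 1.
#' @param gc_min,gc_max Optional GC-fraction bounds in `[0, 1]`.
#' @param max_gc_half_diff Optional cap on the half-vs-half GC difference.
#' @return A validated `oligocover_config` list.
#' @export
oligocover_config <- function(primer_length = 20,
                              min_primer_group_size = 1,
                              min_sequence_group_size = 2,
                              decimals = 4,
                              gc_min = NULL, gc_max = NULL,
                              max_gc_half_diff = NULL) {
  chk_int <- function(x, name, lo) {
    if (!is.numeric(x) || length(x) != 1 || x != round(x) || x < lo) {
      abort(paste0("`", name, "` must be a single integer >= ", lo, "."),
            class = "oligocover_param_error")
    }
    as.integer(x)
  }
  cfg <- list(
    primer_length = chk_int(primer_length, "primer_length", 2),
    min_primer_group_size = chk_int(min_primer_group_size, "min_primer_group_size", 1),
    min_sequence_group_size = chk_int(min_sequence_group_size, "min_sequence_group_size", 1),
    decimals = chk_int(decimals, "decimals", 1),
    gc_min = gc_min, gc_max = gc_max, max_gc_half_diff = max_gc_half_diff
  )
  if (!is.null(gc_min) && !is.null(gc_max) && gc_min > gc_max) {
    abort("`gc_min` must not exceed `gc_max`.", class = "oligocover_param_error")
  }
  structure(cfg, class = "oligocover_config")
}

#' Write / read a configuration file
#'
#' Serialises a configuration as simple `key: value` YAML so a run can be
#' reproduced exactly from its config file. Unset optional filters are
#' written as `~` (null).
#'
#' @param config An [oligocover_config()].
#' @param path File path.
#' @return `write_config()` returns `path` invisibly; `read_config()` an
#'   `oligocover_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "oligocover_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(oligocover_config, vals[!vapply(vals, is.null, logical(1))])
}

#' Design a near-optimal primer/probe panel
#'
#' The full design pipeline: read the FASTA (or take an already-parsed
#' sequence table), enumerate sliding-window primer candidates, apply the
#' optional GC screens, group candidates into clusters of identical sequence
#' coverage, drop clusters below the size cut-offs, rank clusters by size
#' with rounded cumulative coverage, and collapse clusters sharing a
#' cumulative value. The retained clusters approximate a minimal set cover
#' of the input sequences; the whole computation is deterministic and scales
#' linearly with total input bases.
#'
#' @param x Path to a FASTA file, or a sequence table (tibble with `seq_id`,
#'   `header`, `sequence`) such as [read_fasta()] or [synthesize_fasta()]
#'   returns.
#' @param ... Parameters forwarded to [oligocover_config()], e.g.
#'   `primer_length`, `min_sequence_group_size`, `gc_min`.
#' @param config A ready-made [oligocover_config()]; overrides `...`.
#' @param verbose Log per-stage counts to the console.
#' @return An `oligocover_result`; see [build_result()].
#' @examples
#' recs <- synthesize_fasta(n_sequences = 12, bases_per_sequence = 120,
#'                          mode = "family", n_ancestors = 3,
#'                          substitution_rate = 0.02, seed = 1)
#' res <- design_primers(recs, min_sequence_group_size = 1)
#' glance(res)
#' @export
design_primers <- function(x, ..., config = NULL, verbose = FALSE) {
  if (is.null(config)) config <- oligocover_config(...)
  stopifnot(inherits(config, "oligocover_config"))
  records <- if (is.character(x) && length(x) == 1) read_fasta(x) else {
    stopifnot(is.data.frame(x),
              all(c("seq_id", "header", "sequence") %in% names(x)))
    as_tibble(x)
  }
  say <- function(...) if (verbose) message(sprintf(...))
  say("input: %d sequences, %d bases", nrow(records), sum(nchar(records$sequence)))

  index <- enumerate_candidates(records, k = config$primer_length)
  pre_gc <- index_universe(index)
  say("candidates: %d distinct %d-mers", nrow(index$entries), index$k)

  index <- apply_gc_filters(index, gc_min = config$gc_min,
                            gc_max = config$gc_max,
                            max_half_diff = config$max_gc_half_diff)
  post_gc <- index_universe(index)
  say("after GC filters: %d candidates", nrow(index$entries))

  clusters <- build_clusters(index)
  clusters <- filter_clusters(clusters,
                              min_primer_group_size = config$min_primer_group_size,
                              min_sequence_group_size = config$min_sequence_group_size)
  post_cutoff <- cluster_coverage_union(clusters)
  say("clusters after size cut-offs: %d", nrow(clusters))

  ranked <- rank_and_cumulate(clusters, n_sequences = nrow(records),
                              decimals = config$decimals)
  ranked <- deduplicate_by_cumulative(ranked)
  say("clusters after cumulative deduplication: %d", nrow(ranked))

  build_result(records, ranked, config,
               stage_universes = list(pre_gc = pre_gc, post_gc = post_gc,
                                      post_cutoff = post_cutoff))
}

#' Run the pipeline and write all outputs
#'
#' Convenience wrapper: [design_primers()] followed by [write_result()].
#'
#' @inheritParams design_primers
#' @param output_dir Directory for the output tables and heatmap.
#' @param strict Omit the diagnostic `reason` column from the excluded table.
#' @return The `oligocover_result`, invisibly.
#' @export
run_pipeline <- function(x, output_dir, ..., config = NULL, strict = FALSE,
                         verbose = FALSE) {
  result <- design_primers(x, ..., config = config, verbose = verbose)
  write_result(result, output_dir, strict = strict)
  invisible(result)
}
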