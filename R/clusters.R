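#' Group primer candidates into clusters by identical coverage
#'
#' The core reduction step: candidates are partitioned by exact equality of
#' their coverage sets, so each *primer cluster* is a maximal set of k-mers
#' occurring in exactly the same input sequences, and its *sequence group* is
#' that shared coverage set. Any one primer from a cluster covers the whole
#' sequence group, which is what lets the later ranking treat clusters — not
#' individual k-mers — as the units of the set-cover approximation.
#'
#' @param index A `candidate_index`, typically after [apply_gc_filters()].
#' @return A tibble with one row per cluster: list-columns `primers` (sorted
#'   k-mers) and `seq_ids` (sorted coverage set), plus `primer_group_size`
#'   and `sequence_group_size`.
#' @export
build_clusters <- function(index) {
  stopifnot(inherits(index, "candidate_index"))
  entries <- index$entries
  if (nrow(entries) == 0) {
    return(tibble(
      primers = list(), seq_ids = list(),
      primer_group_size = integer(0), sequence_group_size = integer(0)
    ))
  }
  lens <- lengths(entries$seq_ids)
  key <- character(nrow(entries))
  key[lens == 1L] <- as.character(unlist(entries$seq_ids[lens == 1L]))
  multi <- which(lens > 1L)
  key[multi] <- vapply(entries$seq_ids[multi], paste, character(1), collapse = ",")
  entries |>
    dplyr::mutate(coverage_key = key) |>
    dplyr::group_by(.data$coverage_key) |>
    dplyr::summarise(
      primers = list(sort(.data$kmer)),
      seq_ids = .data$seq_ids[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      primer_group_size = lengths(.data$primers),
      sequence_group_size = lengths(.data$seq_ids)
    ) |>
    dplyr::select(-"coverage_key")
}

#' Drop clusters below the size cut-offs
#'
#' Removes clusters whose primer group or sequence group is smaller than the
#' user cut-offs. A minimum sequence group size of 2 discards primers private
#' to a single sequence (usually uninformative for multiplexing); setting it
#' to 1 guarantees every coverable sequence can be covered, which is the
#' setting used when small inputs must be fully processed.
#'
#' @param clusters Cluster tibble from [build_clusters()].
#' @param min_primer_group_size,min_sequence_group_size Integer cut-offs
#'   (each at least 1).
#' @return The surviving clusters. Removing everything is not an error.
#' @export
filter_clusters <- function(clusters, min_primer_group_size = 1,
                            min_sequence_group_size = 2) {
  stopifnot(min_primer_group_size >= 1, min_sequence_group_size >= 1)
  dplyr::filter(
    clusters,
    .data$primer_group_size >= min_primer_group_size,
    .data$sequence_group_size >= min_sequence_group_size
  )
}

#' Rank clusters and compute rounded cumulative coverage
#'
#' Orders clusters by size — sequence group size descending (coverage is the
#' quantity being maximised), then primer group size descending, with a final
#' deterministic tie-break on the lexicographically smallest primer — and
#' walks the order maintaining a running union of sequence groups. Each
#' cluster's `cumulative_coverage` is the fraction of all input sequences in
#' the union up to and including it, rounded half-away-from-zero to
#' `decimals` places. The rounded values drive the subsequent deduplication:
#' coarser rounding merges clusters of nearly identical marginal value.
#'
#' @param clusters Cluster tibble ([build_clusters()] / [filter_clusters()]).
#' @param n_sequences Total number of input sequences (denominator).
#' @param decimals Rounding precision `d >= 1` for the cumulative values;
#'   default 4.
#' @return The clusters in rank order with `cluster_id` (1..m) and
#'   `cumulative_coverage` columns; attributes `n_sequences` and `decimals`
#'   record the walk's parameters.
#' @export
rank_and_cumulate <- function(clusters, n_sequences, decimals = 4) {
  stopifnot(n_sequences >= 1, decimals >= 1)
  if (nrow(clusters) == 0) {
    out <- dplyr::mutate(clusters, cluster_id = integer(0),
                         cumulative_coverage = numeric(0))
    return(set_ranking_attrs(out, n_sequences, decimals))
  }
  ranked <- clusters |>
    dplyr::mutate(.first_primer = purrr::map_chr(.data$primers, 1)) |>
    dplyr::arrange(
      dplyr::desc(.data$sequence_group_size),
      dplyr::desc(.data$primer_group_size),
      .data$.first_primer
    ) |>
    dplyr::select(-".first_primer")
  covered <- logical(n_sequences)
  cum <- numeric(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    covered[ranked$seq_ids[[i]]] <- TRUE
    cum[i] <- sum(covered) / n_sequences
  }
  ranked <- ranked |>
    dplyr::mutate(
      cluster_id = dplyr::row_number(),
      cumulative_coverage = round_half_up(cum, decimals)
    ) |>
    dplyr::relocate("cluster_id")
  set_ranking_attrs(ranked, n_sequences, decimals)
}

#' Collapse clusters sharing a cumulative-coverage value
#'
#' Clusters whose rounded cumulative coverage is identical added (at the
#' chosen precision) nothing distinguishable to the running coverage; within
#' each such group only the clusters attaining the maximal sequence group
#' size — and among those the maximal primer group size — are kept, all
#' remaining ties retained. This prunes clusters of high redundancy or
#' near-identical coverage. Cumulative values describe the pre-reduction
#' walk and are deliberately not recomputed; cluster ids are reassigned
#' contiguously.
#'
#' @param ranked Output of [rank_and_cumulate()].
#' @return The reduced ranking, same columns and attributes.
#' @export
deduplicate_by_cumulative <- function(ranked) {
  if (nrow(ranked) == 0) return(ranked)
  n_sequences <- attr(ranked, "n_sequences")
  decimals <- attr(ranked, "decimals")
  out <- ranked |>
    dplyr::group_by(.data$cumulative_coverage) |>
    dplyr::filter(.data$sequence_group_size == max(.data$sequence_group_size)) |>
    dplyr::filter(.data$primer_group_size == max(.data$primer_group_size)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cluster_id) |>
    dplyr::mutate(cluster_id = dplyr::row_number())
  set_ranking_attrs(out, n_sequences, decimals)
}

set_ranking_attrs <- function(x, n_sequences, decimals) {
  attr(x, "n_sequences") <- n_sequences
  attr(x, "decimals") <- decimals
  x
}

#' Union of the sequence groups of a cluster set
#'
#' @param clusters A cluster tibble with a `seq_ids` list-column.
#' @return Sorted integer vector of covered seq_ids.
#' @export
cluster_coverage_union <- function(clusters) {
  sort(unique(unlist(clusters$seq_ids, use.names = FALSE))) %||% integer(0)
}

# Round half away from zero to d decimals (base round() rounds half to even).
round_half_up <- function(x, d) {
  p <- 10^d
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
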