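#' Build the cluster-by-sequence coverage matrix
#'
#' A TRUE/FALSE incidence table: rows are primer clusters in rank order,
#' columns are all input sequence ids in ascending order, and a cell is TRUE
#' iff the sequence belongs to the cluster's sequence group. Row sums equal
#' the sequence group sizes; an all-FALSE column marks an excluded sequence.
#'
#' @param ranked A ranked cluster tibble ([rank_and_cumulate()] or
#'   [deduplicate_by_cumulative()]).
#' @param n_sequences Total input sequence count (number of columns).
#' @return A logical matrix with `cluster_id` rownames and `seq_id` colnames.
#' @export
coverage_matrix <- function(ranked, n_sequences) {
  m <- matrix(FALSE, nrow = nrow(ranked), ncol = n_sequences,
              dimnames = list(ranked$cluster_id, seq_len(n_sequences)))
  for (i in seq_len(nrow(ranked))) {
    m[i, ranked$seq_ids[[i]]] <- TRUE
  }
  m
}

#' Assemble the five-element design result
#'
#' Bundles the pipeline's outputs into an `oligocover_result`, a classed list
#' with exactly five elements: `description` (named list summarising input
#' and parameters), `conversion_table`, `primer_candidates` (the cluster
#' table with comma-joined primers and seq_ids), `excluded_sequences`
#' (seq_id, header and a diagnostic `reason`), and `primer_matrix` (the
#' TRUE/FALSE coverage matrix). Every input sequence appears either in at
#' least one cluster's sequence group or in `excluded_sequences`, never both.
#'
#' Exclusion reasons, assigned by the earliest pipeline stage at which a
#' sequence lost its last covering candidate: `too_short` (shorter than the
#' primer length), `filtered_gc` (all its candidates failed a GC screen),
#' `filtered_cluster_cutoffs` (all its clusters fell below the size
#' cut-offs), `no_shared_candidate_surviving` (no usable window at all, or
#' coverage lost in the cumulative deduplication).
#'
#' @param records Sequence table from [read_fasta()].
#' @param ranked Final ranked cluster tibble.
#' @param config An [oligocover_config()] (the parameters actually used).
#' @param stage_universes Optional list with integer-vector elements
#'   `pre_gc`, `post_gc`, `post_cutoff` — the covered sequence sets after the
#'   corresponding stages — used to attribute exclusion reasons. Without it,
#'   reasons beyond `too_short` fall back to `no_shared_candidate_surviving`.
#' @return An `oligocover_result`.
#' @export
build_result <- function(records, ranked, config = oligocover_config(),
                         stage_universes = NULL) {
  n <- nrow(records)
  k <- config$primer_length
  final_union <- cluster_coverage_union(ranked)
  excluded_ids <- setdiff(records$seq_id, final_union)
  reason <- vapply(excluded_ids, function(id) {
    if (nchar(records$sequence[records$seq_id == id]) < k) return("too_short")
    if (!is.null(stage_universes)) {
      if (id %in% stage_universes$pre_gc && !(id %in% stage_universes$post_gc)) {
        return("filtered_gc")
      }
      if (id %in% stage_universes$post_gc && !(id %in% stage_universes$post_cutoff)) {
        return("filtered_cluster_cutoffs")
      }
    }
    "no_shared_candidate_surviving"
  }, character(1))
  excluded <- tibble(
    seq_id = excluded_ids,
    header = records$header[match(excluded_ids, records$seq_id)],
    reason = reason
  )
  candidates_tbl <- tibble(
    cluster_id = ranked$cluster_id,
    primers = purrr::map_chr(ranked$primers, paste, collapse = ","),
    seq_ids = purrr::map_chr(ranked$seq_ids, paste, collapse = ","),
    primer_group_size = ranked$primer_group_size,
    sequence_group_size = ranked$sequence_group_size,
    cumulative_coverage = ranked$cumulative_coverage
  )
  description <- list(
    n_sequences = n,
    total_bases = sum(nchar(records$sequence)),
    n_primer_clusters = nrow(ranked),
    n_primer_candidates = sum(ranked$primer_group_size),
    n_excluded_sequences = nrow(excluded),
    final_cumulative_coverage = if (nrow(ranked)) ranked$cumulative_coverage[nrow(ranked)] else 0,
    parameters = config[c("primer_length", "min_primer_group_size",
                          "min_sequence_group_size", "decimals",
                          "gc_min", "gc_max", "max_gc_half_diff")]
  )
  structure(
    list(
      description = description,
      conversion_table = conversion_table(records),
      primer_candidates = candidates_tbl,
      excluded_sequences = excluded,
      primer_matrix = coverage_matrix(ranked, n)
    ),
    class = "oligocover_result"
  )
}

#' @export
print.oligocover_result <- function(x, ...) {
  d <- x$description
  cat("<oligocover_result>\n",
      "  sequences: ", d$n_sequences, " (", d$total_bases, " bases)\n",
      "  primer clusters: ", d$n_primer_clusters,
      " (", d$n_primer_candidates, " candidate primers)\n",
      "  excluded sequences: ", d$n_excluded_sequences, "\n",
      "  final cumulative coverage: ", d$final_cumulative_coverage, "\n",
      "  primer length k = ", d$parameters$primer_length, "\n", sep = "")
  invisible(x)
}

#' Access the primer cluster table of a design result
#'
#' @param x An `oligocover_result`.
#' @param ... Unused.
#' @return The `primer_candidates` tibble: one row per retained cluster with
#'   comma-joined primers and sequence ids, group sizes and cumulative
#'   coverage.
#' @export
primers <- function(x, ...) UseMethod("primers")

#' @export
primers.oligocover_result <- function(x, ...) x$primer_candidates

#' Access the per-sequence coverage of a design result
#'
#' @param x An `oligocover_result`.
#' @param ... Unused.
#' @return A tibble with one row per covered (non-excluded) sequence:
#'   `seq_id` and the list-column `cluster_ids` of clusters covering it —
#'   the transpose view of the primer matrix.
#' @export
sequences <- function(x, ...) UseMethod("sequences")

#' @export
sequences.oligocover_result <- function(x, ...) {
  m <- x$primer_matrix
  covered_cols <- which(colSums(m) > 0)
  tibble(
    seq_id = as.integer(colnames(m)[covered_cols]),
    cluster_ids = purrr::map(covered_cols, function(j) {
      as.integer(rownames(m)[m[, j]])
    })
  )
}

#' Tidy view of a design result: the primer cluster table
#'
#' @param x An `oligocover_result`.
#' @param ... Unused.
#' @return One row per retained cluster, as [primers()].
#' @method tidy oligocover_result
#' @export
tidy.oligocover_result <- function(x, ...) primers(x)

#' One-row summary of a design result
#'
#' @param x An `oligocover_result`.
#' @param ... Unused.
#' @return A one-row tibble of sequence, base, cluster and exclusion counts
#'   plus the final cumulative coverage.
#' @method glance oligocover_result
#' @export
glance.oligocover_result <- function(x, ...) {
  d <- x$description
  tibble(
    n_sequences = d$n_sequences,
    total_bases = d$total_bases,
    n_primer_clusters = d$n_primer_clusters,
    n_primer_candidates = d$n_primer_candidates,
    n_excluded_sequences = d$n_excluded_sequences,
    final_cumulative_coverage = d$final_cumulative_coverage
  )
}

#' Heatmap of primer-cluster coverage
#'
#' Two-colour heatmap of the TRUE/FALSE primer matrix: sequence ids on the
#' x axis, primer clusters in rank order from the top on the y axis, covered
#' cells dark, uncovered light. The blocky dark regions show which clusters
#' jointly tile the input diversity.
#'
#' @param matrix A logical coverage matrix from [coverage_matrix()] (or the
#'   `primer_matrix` element of a result).
#' @param out Optional output path; the image format follows the file
#'   extension (`.png` default choice, `.pdf`, `.svg` ...).
#' @param width,height,dpi Device size passed to [ggplot2::ggsave()] when
#'   `out` is given.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_heatmap <- function(matrix, out = NULL, width = 7, height = 5, dpi = 150) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0 || ncol(matrix) == 0) {
    abort(paste("The coverage matrix is empty: all sequences were excluded.",
                "Relax the cluster size cut-offs or GC filters."),
          class = "oligocover_input_error")
  }
  long <- tibble(
    cluster = factor(rep(rownames(matrix), times = ncol(matrix)),
                     levels = rev(rownames(matrix))),
    seq_id = factor(rep(colnames(matrix), each = nrow(matrix)),
                    levels = colnames(matrix)),
    covered = as.vector(matrix)
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$seq_id, y = .data$cluster,
                                          fill = .data$covered)) +
    ggplot2::geom_tile(colour = NA) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "grey95"),
                               guide = "none") +
    ggplot2::labs(x = "Sequence id", y = "Primer cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (!is.null(out)) {
    ggplot2::ggsave(out, plot = p, width = width, height = height, dpi = dpi)
    return(invisible(p))
  }
  p
}

#' Autoplot method for a design result: the coverage heatmap
#'
#' @param object An `oligocover_result`.
#' @param ... Unused.
#' @return A ggplot object; see [plot_heatmap()].
#' @method autoplot oligocover_result
#' @export
autoplot.oligocover_result <- function(object, ...) {
  plot_heatmap(object$primer_matrix)
}

#' @export
plot.oligocover_result <- function(x, ...) print(autoplot.oligocover_result(x))

#' Write a design result to disk
#'
#' Writes `description.txt`, `conversion_table.tsv`, `primer_candidates.tsv`,
#' `excluded_sequences.tsv` and `primer_matrix.tsv` (header row of sequence
#' ids, rows led by `cluster_id`, cells `TRUE`/`FALSE`) into `dir`, plus
#' `heatmap.png` when any cluster was retained. Output is deterministic:
#' identical input and configuration give byte-identical tables.
#'
#' @param result An `oligocover_result`.
#' @param dir Output directory, created if needed.
#' @param strict If TRUE, omit the diagnostic `reason` column from
#'   `excluded_sequences.tsv`.
#' @param heatmap If TRUE (default) also render `heatmap.png` when possible.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir, strict = FALSE, heatmap = TRUE) {
  stopifnot(inherits(result, "oligocover_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  d <- result$description
  desc_lines <- c(
    paste0("n_sequences\t", d$n_sequences),
    paste0("total_bases\t", d$total_bases),
    paste0("n_primer_clusters\t", d$n_primer_clusters),
    paste0("n_primer_candidates\t", d$n_primer_candidates),
    paste0("n_excluded_sequences\t", d$n_excluded_sequences),
    paste0("final_cumulative_coverage\t", d$final_cumulative_coverage),
    vapply(names(d$parameters), function(nm) {
      v <- d$parameters[[nm]]
      paste0(nm, "\t", if (is.null(v)) "unset" else v)
    }, character(1))
  )
  writeLines(desc_lines, file.path(dir, "description.txt"))
  tsv(result$conversion_table, "conversion_table.tsv")
  tsv(result$primer_candidates, "primer_candidates.tsv")
  excl <- result$excluded_sequences
  if (strict) excl <- dplyr::select(excl, -"reason")
  tsv(excl, "excluded_sequences.tsv")
  pm <- result$primer_matrix
  pm_df <- data.frame(cluster_id = rownames(pm), pm, check.names = FALSE)
  tsv(pm_df, "primer_matrix.tsv")
  if (heatmap && nrow(pm) > 0 && ncol(pm) > 0) {
    plot_heatmap(pm, out = file.path(dir, "heatmap.png"))
  }
  invisible(dir)
}
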