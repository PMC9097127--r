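#' Generate synthetic DNA sequence sets
#'
#' Seeded generator for benchmark-style FASTA inputs. `uniform_random` draws
#' every base i.i.d. uniformly from `A/C/G/T` — the regime of the large
#' scaling benchmarks, where distinct sequences almost never share a 20-mer.
#' `family` draws `n_ancestors` random ancestors and emits mutated copies
#' with i.i.d. substitutions at `substitution_rate` (each substituted base
#' replaced by a different base, uniformly), so that family members share
#' long exact k-mers and realistic cluster structure emerges — the input
#' class primer clustering is actually for.
#'
#' @param n_sequences Number of sequences to generate.
#' @param bases_per_sequence Length of every sequence (equal lengths).
#' @param mode `"uniform_random"` or `"family"`.
#' @param n_ancestors Family mode: number of ancestral sequences; copies are
#'   assigned round-robin.
#' @param substitution_rate Family mode: per-base substitution probability
#'   in `[0, 1]`.
#' @param seed Optional integer; identical spec + seed gives an identical
#'   sequence set (the generator uses its own RNG stream and leaves the
#'   global RNG state untouched).
#' @param out Optional path: also write the set as FASTA.
#' @return A sequence table (tibble of `seq_id`, `header`, `sequence`).
#' @export
synthesize_fasta <- function(n_sequences, bases_per_sequence,
                             mode = c("uniform_random", "family"),
                             n_ancestors = 1, substitution_rate = 0.02,
                             seed = NULL, out = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_sequences >= 1, bases_per_sequence >= 1,
            substitution_rate >= 0, substitution_rate <= 1, n_ancestors >= 1)
  bases <- c("A", "C", "G", "T")
  runner <- function() {
    if (mode == "uniform_random") {
      seqs <- vapply(seq_len(n_sequences), function(i) {
        paste(sample(bases, bases_per_sequence, replace = TRUE), collapse = "")
      }, character(1))
      headers <- paste0("random_", seq_len(n_sequences))
    } else {
      ancestors <- replicate(n_ancestors,
                             sample(bases, bases_per_sequence, replace = TRUE),
                             simplify = FALSE)
      anc_of <- rep_len(seq_len(n_ancestors), n_sequences)
      seqs <- vapply(seq_len(n_sequences), function(i) {
        chars <- ancestors[[anc_of[i]]]
        hit <- runif(bases_per_sequence) < substitution_rate
        if (any(hit)) {
          chars[hit] <- vapply(chars[hit], function(b) {
            sample(setdiff(bases, b), 1)
          }, character(1))
        }
        paste(chars, collapse = "")
      }, character(1))
      headers <- paste0("family_", anc_of, "_copy_", seq_len(n_sequences))
    }
    tibble(seq_id = seq_len(n_sequences), header = headers, sequence = seqs)
  }
  records <- if (is.null(seed)) runner() else with_local_seed(seed, runner())
  if (!is.null(out)) write_fasta(records, out)
  records
}

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Brute-force candidate multimap (test oracle)
#'
#' Reference implementation of the candidate index: a plain double loop that
#' extracts every length-`k` substring of every sequence one position at a
#' time, skipping windows with non-`A/C/G/T` letters, with no vectorisation
#' or indexing tricks. Used only to cross-check [enumerate_candidates()].
#'
#' @inheritParams enumerate_candidates
#' @return A tibble of `kmer` and sorted integer list-column `seq_ids`,
#'   ordered by `kmer`.
#' @export
naive_candidate_multimap <- function(records, k) {
  acc <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(records))) {
    chars <- strsplit(records$sequence[r], "", fixed = TRUE)[[1]]
    ok <- chars %in% c("A", "C", "G", "T")
    L <- length(chars)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      if (all(ok[i:(i + k - 1)])) {
        km <- paste(chars[i:(i + k - 1)], collapse = "")
        acc[[km]] <- c(acc[[km]], records$seq_id[r])
      }
    }
  }
  kmers <- sort(ls(acc))
  tibble(
    kmer = kmers,
    seq_ids = purrr::map(kmers, function(km) sort(unique(acc[[km]])))
  )
}

#' Exact minimum set cover by exhaustive search (test oracle)
#'
#' Finds the minimum number of families whose union equals the coverable
#' universe (the union of all families) by trying all subsets in order of
#' increasing size. Exponential — intended only for tiny test instances.
#'
#' @param universe Integer vector (informational; the coverable universe is
#'   the union of `families`).
#' @param families List of integer vectors, at most 20 of them.
#' @return The minimum cover cardinality (integer).
#' @export
exact_min_cover <- function(universe, families) {
  if (length(families) == 0) {
    if (length(universe) > 0) {
      abort("No families given but the universe is non-empty.",
            class = "oligocover_param_error")
    }
    return(0L)
  }
  stopifnot(length(families) <= 20)
  target <- sort(unique(unlist(families)))
  n <- length(families)
  for (m in seq_len(n)) {
    combos <- utils::combn(n, m, simplify = FALSE)
    for (cc in combos) {
      if (setequal(unlist(families[cc]), target)) return(m)
    }
  }
  n
}

#' Greedy set cover (test oracle)
#'
#' Classic greedy approximation: repeatedly pick the family covering the
#' most still-uncovered elements (ties broken by list order). Its size is
#' always >= the exact minimum and <= the number of families.
#'
#' @inheritParams exact_min_cover
#' @return The greedy cover cardinality (integer).
#' @export
greedy_cover <- function(universe, families) {
  target <- sort(unique(unlist(families)))
  uncovered <- target
  size <- 0L
  while (length(uncovered) > 0) {
    gains <- vapply(families, function(f) length(intersect(f, uncovered)),
                    integer(1))
    best <- which.max(gains)
    if (gains[best] == 0) break
    uncovered <- setdiff(uncovered, families[[best]])
    size <- size + 1L
  }
  size
}

#' Linear-scaling harness
#'
#' Generates inputs of growing size (`bases_per_sequence` scaled by each
#' multiplier), runs the full design pipeline on each, and records the total
#' bases, the exact sliding-window count (the deterministic linearity
#' witness: it equals `sum(L - k + 1)` and grows exactly linearly in total
#' bases) and the wall-clock time (informational; hardware-dependent).
#'
#' @param base_n_sequences,base_bases_per_sequence Size of the smallest
#'   input.
#' @param multipliers Ascending integer multipliers applied to
#'   `bases_per_sequence`.
#' @param k Primer length used in the runs.
#' @param mode,seed Passed to [synthesize_fasta()] (one seed per multiplier,
#'   derived as `seed + multiplier`).
#' @param min_sequence_group_size Cut-off used in the runs; 1 ensures even
#'   the smallest inputs are fully processed.
#' @param replicates Pipeline runs per multiplier; the reported `wall_time`
#'   is the minimum over replicates, which suppresses transient system-load
#'   spikes when the timings are used for scaling comparisons.
#' @param out Optional path for a tab-separated report.
#' @return A tibble with columns `multiplier`, `total_bases`,
#'   `window_count`, `wall_time` (seconds).
#' @export
scaling_harness <- function(base_n_sequences, base_bases_per_sequence,
                            multipliers, k = 20, mode = "uniform_random",
                            seed = 1, min_sequence_group_size = 1,
                            replicates = 1, out = NULL) {
  stopifnot(!is.unsorted(multipliers), replicates >= 1)
  rows <- purrr::map(multipliers, function(m) {
    records <- synthesize_fasta(base_n_sequences, base_bases_per_sequence * m,
                                mode = mode, seed = seed + m)
    elapsed <- min(vapply(seq_len(replicates), function(r) {
      system.time(
        design_primers(records, primer_length = k,
                       min_sequence_group_size = min_sequence_group_size)
      )[["elapsed"]]
    }, numeric(1)))
    tibble(
      multiplier = m,
      total_bases = sum(nchar(records$sequence)),
      window_count = window_count(records, k),
      wall_time = elapsed
    )
  })
  report <- dplyr::bind_rows(rows)
  if (!is.null(out)) {
    utils::write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
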