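#' Enumerate k-length primer candidates by sliding window
#'
#' Decomposes every input sequence into all of its length-`k` subsequences
#' (one window per start position) and indexes each distinct k-mer by the set
#' of sequence ids that contain it anywhere — its *coverage*. Windows that
#' contain any letter other than `A/C/G/T` (including `N` and IUPAC ambiguity
#' codes) are skipped rather than expanded: candidates are exact substrings,
#' and degenerate expansion would change the coverage semantics. Sequences
#' shorter than `k` contribute no windows and are reported downstream as
#' excluded.
#'
#' @param records A sequence table from [read_fasta()].
#' @param k Primer candidate length in bases (integer, at least 2).
#'   Defaults to 20 nt, the conventional primer length; for adjacent-probe
#'   designs a length-20 candidate can be read as two abutting 10-mers.
#' @return A `candidate_index`: a list with `entries` (tibble of `kmer` and
#'   list-column `seq_ids`, the sorted integer coverage set), `k` and
#'   `n_sequences`.
#' @examples
#' recs <- tibble::tibble(seq_id = 1L, header = "h", sequence = "ACGTAC")
#' enumerate_candidates(recs, k = 4)$entries
#' @export
enumerate_candidates <- function(records, k = 20) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 2) {
    abort("`k` must be a single integer >= 2.", class = "oligocover_param_error")
  }
  k <- as.integer(k)
  if (all(nchar(records$sequence) < k)) {
    abort(paste0("No candidates producible: every sequence is shorter than k = ", k, "."),
          class = "oligocover_input_error")
  }
  kmer_sets <- purrr::map(records$sequence, function(s) {
    w <- sliding_windows(s, k)
    unique(w[!stringr::str_detect(w, "[^ACGT]")])
  })
  sid <- rep(records$seq_id, lengths(kmer_sets))
  km <- unlist(kmer_sets, use.names = FALSE)
  # Group (kmer, seq_id) pairs by kmer via one radix sort; per-group work is
  # vectorised for the (dominant) singleton runs so the step stays linear.
  o <- order(km, sid, method = "radix")
  km <- km[o]
  sid <- sid[o]
  starts <- which(!duplicated(km))
  ends <- c(starts[-1] - 1L, length(km))
  lens <- ends - starts + 1L
  seq_ids <- vector("list", length(starts))
  single <- lens == 1L
  seq_ids[single] <- as.list(sid[starts[single]])
  for (i in which(!single)) seq_ids[[i]] <- sid[starts[i]:ends[i]]
  entries <- tibble(kmer = km[starts], seq_ids = seq_ids)
  new_candidate_index(entries, k = k, n_sequences = nrow(records))
}

new_candidate_index <- function(entries, k, n_sequences) {
  structure(
    list(entries = entries, k = k, n_sequences = n_sequences),
    class = "candidate_index"
  )
}

#' @export
print.candidate_index <- function(x, ...) {
  cat("<candidate_index> ", nrow(x$entries), " distinct ", x$k, "-mers over ",
      x$n_sequences, " sequences (", length(index_universe(x)),
      " covered)\n", sep = "")
  invisible(x)
}

#' Set of sequence ids covered by at least one candidate
#'
#' @param index A `candidate_index`.
#' @return Sorted integer vector of covered seq_ids.
#' @export
index_universe <- function(index) {
  sort(unique(unlist(index$entries$seq_ids, use.names = FALSE))) %||% integer(0)
}

# All length-k windows of one sequence (0 windows when nchar(s) < k).
sliding_windows <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, 1:(L - k + 1), k:L)
}

#' Total sliding-window count for a sequence set
#'
#' Closed form `sum(max(0, L_i - k + 1))`, the number of windows the
#' enumeration considers. Exactly linear in total bases for fixed `k`, which
#' makes it the deterministic witness for the pipeline's linear scaling.
#'
#' @param records A sequence table.
#' @param k Window length.
#' @return A single integer (as double, to avoid overflow on large inputs).
#' @export
window_count <- function(records, k) {
  sum(pmax(0, nchar(records$sequence) - k + 1))
}

#' GC fraction of DNA strings
#'
#' Proportion of `G` and `C` bases; a standard proxy for hybridisation
#' stability. Vectorised over `s`.
#'
#' @param s Character vector of non-empty `A/C/G/T` strings.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' gc_fraction(c("ATGC", "AAAA", "GCGC"))
#' @export
gc_fraction <- function(s) {
  if (length(s) == 0) return(numeric(0))
  if (any(!nzchar(s))) {
    abort("gc_fraction() is undefined for empty strings.",
          class = "oligocover_param_error")
  }
  if (any(stringr::str_detect(s, "[^ACGT]"))) {
    abort("gc_fraction() expects A/C/G/T strings only.",
          class = "oligocover_param_error")
  }
  (stringr::str_count(s, "G") + stringr::str_count(s, "C")) / nchar(s)
}

#' Absolute GC-fraction difference between the two halves of a primer
#'
#' Used to screen candidates intended as adjacent probe pairs, where the two
#' halves hybridise side by side and should have comparable stability. For
#' odd lengths the first half takes the extra base (`ceiling(L/2)` bases); a
#' fixed convention is required and this is the one used throughout.
#'
#' @param s Character vector of `A/C/G/T` strings, each of length >= 2.
#' @return Numeric vector of absolute differences in `[0, 1]`.
#' @examples
#' gc_half_difference("AAGG") # halves AA / GG -> 1
#' @export
gc_half_difference <- function(s) {
  if (length(s) == 0) return(numeric(0))
  L <- nchar(s)
  if (any(L < 2)) {
    abort("gc_half_difference() needs strings of length >= 2.",
          class = "oligocover_param_error")
  }
  cut <- ceiling(L / 2)
  abs(gc_fraction(substring(s, 1, cut)) - gc_fraction(substring(s, cut + 1, L)))
}

#' Filter primer candidates on GC content
#'
#' Two independent, optional screens applied to the candidate index before
#' clustering: a total GC-fraction range `[gc_min, gc_max]`, and a cap on the
#' GC-fraction difference between the primer's two halves (see
#' [gc_half_difference()]). Unset bounds impose no constraint, so the default
#' call is the identity. Filtering every candidate out is legal; downstream
#' stages then report all sequences as excluded.
#'
#' @param index A `candidate_index` from [enumerate_candidates()].
#' @param gc_min,gc_max Optional GC-fraction bounds in `[0, 1]`.
#' @param max_half_diff Optional maximum half-vs-half GC difference in `[0, 1]`.
#' @return A filtered `candidate_index`.
#' @export
apply_gc_filters <- function(index, gc_min = NULL, gc_max = NULL,
                             max_half_diff = NULL) {
  stopifnot(inherits(index, "candidate_index"))
  check_frac <- function(x, name) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1 || x < 0 || x > 1)) {
      abort(paste0("`", name, "` must be a single fraction in [0, 1]."),
            class = "oligocover_param_error")
    }
  }
  check_frac(gc_min, "gc_min")
  check_frac(gc_max, "gc_max")
  check_frac(max_half_diff, "max_half_diff")
  if (!is.null(gc_min) && !is.null(gc_max) && gc_min > gc_max) {
    abort("`gc_min` must not exceed `gc_max`.", class = "oligocover_param_error")
  }
  entries <- index$entries
  keep <- rep(TRUE, nrow(entries))
  if (!is.null(gc_min) || !is.null(gc_max)) {
    gc <- gc_fraction(entries$kmer)
    if (!is.null(gc_min)) keep <- keep & gc >= gc_min
    if (!is.null(gc_max)) keep <- keep & gc <= gc_max
  }
  if (!is.null(max_half_diff)) {
    keep <- keep & gc_half_difference(entries$kmer) <= max_half_diff
  }
  new_candidate_index(entries[keep, , drop = FALSE],
                      k = index$k, n_sequences = index$n_sequences)
}
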