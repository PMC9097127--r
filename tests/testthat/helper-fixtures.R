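# Shared fixture builders: everything is generated in code, seeded.

records_tbl <- function(...) {
  seqs <- toupper(c(...))
  tibble::tibble(seq_id = seq_along(seqs),
                 header = paste0("s", seq_along(seqs)),
                 sequence = seqs)
}

# Confirm by direct substring search that `kmer` occurs in exactly the
# sequences `ids` of `records` (the cluster-soundness oracle).
occurs_exactly_in <- function(kmer, ids, records) {
  hits <- records$seq_id[grepl(kmer, records$sequence, fixed = TRUE)]
  setequal(hits, ids)
}

# Per-kmer GC recount with no vectorised string ops (the GC-filter oracle).
gc_recount <- function(kmer) {
  chars <- strsplit(kmer, "")[[1]]
  sum(chars == "G" | chars == "C") / length(chars)
}

gc_half_recount <- function(kmer) {
  chars <- strsplit(kmer, "")[[1]]
  cut <- ceiling(length(chars) / 2)
  f <- function(v) sum(v == "G" | v == "C") / length(v)
  abs(f(chars[seq_len(cut)]) - f(chars[-seq_len(cut)]))
}

random_kmers <- function(n, k, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, character(1))
}

# Cluster tibble built directly from lists of (primers, seq_ids) pairs.
clusters_tbl <- function(...) {
  specs <- list(...)
  tibble::tibble(
    primers = lapply(specs, function(s) sort(s$primers)),
    seq_ids = lapply(specs, function(s) sort(as.integer(s$seq_ids))),
    primer_group_size = vapply(specs, function(s) length(s$primers), integer(1)),
    sequence_group_size = vapply(specs, function(s) length(s$seq_ids), integer(1))
  )
}

# Index built directly from a named list kmer -> integer ids (test shortcut).
index_from_list <- function(entries_list, k, n_sequences) {
  idx <- oligocover:::new_candidate_index(
    tibble::tibble(kmer = names(entries_list),
                   seq_ids = lapply(unname(entries_list), function(x) sort(as.integer(x)))),
    k = k, n_sequences = n_sequences
  )
  idx$entries <- idx$entries[order(idx$entries$kmer), ]
  idx
}
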