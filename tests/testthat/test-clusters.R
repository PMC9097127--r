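test_that("clusters partition candidates by exact coverage equality", {
  idx <- index_from_list(list(AAAA = c(1, 2), CCCC = c(1, 2), GGGG = 3),
                         k = 4, n_sequences = 3)
  cl <- build_clusters(idx)
  expect_equal(nrow(cl), 2)
  shared <- cl[cl$sequence_group_size == 2, ]
  expect_equal(shared$primers[[1]], c("AAAA", "CCCC"))
  expect_equal(shared$seq_ids[[1]], c(1L, 2L))
  expect_equal(cl$seq_ids[cl$sequence_group_size == 1][[1]], 3L)

  # all-distinct coverages: one singleton cluster per candidate
  idx2 <- index_from_list(list(AAAA = 1, CCCC = 2, GGGG = 3), k = 4, n_sequences = 3)
  cl2 <- build_clusters(idx2)
  expect_equal(nrow(cl2), 3)
  expect_true(all(cl2$primer_group_size == 1))
})

test_that("cluster partition on a mutated family matches the brute-force oracle", {
  recs <- synthesize_fasta(10, 200, mode = "family", n_ancestors = 1,
                           substitution_rate = 0.02, seed = 7)
  idx <- enumerate_candidates(recs, 20)
  cl <- build_clusters(idx)

  # oracle: partition the naive multimap by identical coverage sets
  oracle <- naive_candidate_multimap(recs, 20)
  keys <- vapply(oracle$seq_ids, paste, character(1), collapse = ",")
  oracle_partition <- split(oracle$kmer, keys)
  got_partition <- setNames(
    lapply(cl$primers, sort),
    vapply(cl$seq_ids, paste, character(1), collapse = ",")
  )
  expect_setequal(names(got_partition), names(oracle_partition))
  for (key in names(oracle_partition)) {
    expect_equal(got_partition[[key]], sort(oracle_partition[[key]]))
  }
  # every candidate appears in exactly one cluster
  expect_equal(sort(unlist(cl$primers)), oracle$kmer)
})

test_that("size cut-offs drop exactly the undersized clusters", {
  cl <- clusters_tbl(
    list(primers = c("AA", "CC"), seq_ids = c(1, 2)),
    list(primers = "GG", seq_ids = 3)
  )
  kept <- filter_clusters(cl, min_sequence_group_size = 2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$seq_ids[[1]], c(1L, 2L))

  # both thresholds at 1: identity
  expect_equal(filter_clusters(cl, 1, 1), cl)

  # independent recount oracle on a random instance
  set.seed(41)
  rand <- do.call(clusters_tbl, lapply(1:20, function(i) {
    list(primers = random_kmers(sample(1:4, 1), 6, seed = 100 + i),
         seq_ids = sample(1:10, sample(1:5, 1)))
  }))
  kept2 <- filter_clusters(rand, min_primer_group_size = 2,
                           min_sequence_group_size = 3)
  oracle_keep <- vapply(seq_len(nrow(rand)), function(i) {
    length(rand$primers[[i]]) >= 2 && length(rand$seq_ids[[i]]) >= 3
  }, logical(1))
  expect_equal(kept2, rand[oracle_keep, ])
})

test_that("ranking orders by size and accumulates the rounded running union", {
  cl <- clusters_tbl(
    list(primers = c("AAA", "AAC", "AAG"), seq_ids = c(1, 2, 3)),
    list(primers = c("CCC", "CCA"), seq_ids = c(3, 4)),
    list(primers = "GGG", seq_ids = 5)
  )
  ranked <- rank_and_cumulate(cl, n_sequences = 5, decimals = 2)
  expect_equal(ranked$cluster_id, 1:3)
  expect_equal(ranked$sequence_group_size, c(3L, 2L, 1L))
  expect_equal(ranked$cumulative_coverage, c(0.60, 0.80, 1.00))

  single <- rank_and_cumulate(
    clusters_tbl(list(primers = "AAA", seq_ids = 1:4)), n_sequences = 4)
  expect_equal(single$cumulative_coverage, 1)
})

test_that("cumulative rounding is half-away-from-zero, not banker's", {
  # |U|/n = 1/8 = 0.125 -> 0.13 at two decimals (round() would give 0.12)
  ranked <- rank_and_cumulate(
    clusters_tbl(list(primers = "AAA", seq_ids = 1)),
    n_sequences = 8, decimals = 2)
  expect_equal(ranked$cumulative_coverage, 0.13)
})

test_that("cumulative coverage matches a from-scratch union oracle and is monotone", {
  set.seed(13)
  cl <- do.call(clusters_tbl, lapply(1:30, function(i) {
    list(primers = random_kmers(sample(1:3, 1), 8, seed = 200 + i),
         seq_ids = sample(1:15, sample(1:6, 1)))
  }))
  ranked <- rank_and_cumulate(cl, n_sequences = 15, decimals = 4)

  seen <- integer(0)
  for (i in seq_len(nrow(ranked))) {
    seen <- union(seen, ranked$seq_ids[[i]])
    expect_equal(ranked$cumulative_coverage[i],
                 floor(length(seen) / 15 * 1e4 + 0.5) / 1e4)
  }
  expect_true(all(diff(ranked$cumulative_coverage) >= 0))
  expect_equal(ranked$cumulative_coverage[nrow(ranked)],
               floor(length(cluster_coverage_union(cl)) / 15 * 1e4 + 0.5) / 1e4)
})

test_that("deduplication keeps the co-maximal clusters within equal cumulative values", {
  cl <- clusters_tbl(
    list(primers = c("AAA", "AAT", "ACT"), seq_ids = c(1, 2, 3)),  # 0.60
    list(primers = c("CCA", "CCG"), seq_ids = c(1, 2)),            # 0.60 (no new)
    list(primers = c("GGA", "GGC"), seq_ids = c(3, 4))             # 0.80
  )
  ranked <- rank_and_cumulate(cl, n_sequences = 5, decimals = 2)
  expect_equal(ranked$cumulative_coverage, c(0.60, 0.60, 0.80))
  dedup <- deduplicate_by_cumulative(ranked)
  expect_equal(nrow(dedup), 2)
  expect_equal(dedup$cluster_id, 1:2)
  expect_equal(dedup$sequence_group_size, c(3L, 2L))
  # cumulative values are frozen from the pre-reduction walk
  expect_equal(dedup$cumulative_coverage, c(0.60, 0.80))

  # all cumulative values distinct: identity apart from nothing to do
  distinct <- rank_and_cumulate(
    clusters_tbl(
      list(primers = "AAA", seq_ids = c(1, 2)),
      list(primers = "CCC", seq_ids = 3)
    ), n_sequences = 3, decimals = 4)
  expect_equal(deduplicate_by_cumulative(distinct), distinct)
})

test_that("at high precision deduplication removes only zero-contribution clusters", {
  recs <- synthesize_fasta(20, 150, mode = "family", n_ancestors = 4,
                           substitution_rate = 0.03, seed = 17)
  idx <- enumerate_candidates(recs, 20)
  ranked <- rank_and_cumulate(build_clusters(idx), n_sequences = 20, decimals = 10)
  dedup <- deduplicate_by_cumulative(ranked)

  # from-scratch marginal contribution of each ranked cluster
  seen <- integer(0)
  marginal <- integer(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    marginal[i] <- length(setdiff(ranked$seq_ids[[i]], seen))
    seen <- union(seen, ranked$seq_ids[[i]])
  }
  kept_keys <- vapply(dedup$seq_ids, paste, character(1), collapse = ",")
  all_keys <- vapply(ranked$seq_ids, paste, character(1), collapse = ",")
  removed <- !(all_keys %in% kept_keys)
  expect_true(all(marginal[removed] == 0))
  # every cluster that brought new sequences survives; the union is conserved
  expect_true(all(all_keys[marginal > 0] %in% kept_keys))
  expect_equal(cluster_coverage_union(dedup), cluster_coverage_union(ranked))
})

test_that("with cut-offs 1/1 and no GC filters every coverable sequence is covered", {
  recs <- synthesize_fasta(15, 90, mode = "family", n_ancestors = 3,
                           substitution_rate = 0.05, seed = 23)
  recs$sequence[4] <- substr(recs$sequence[4], 1, 10)  # shorter than k
  idx <- enumerate_candidates(recs, 20)
  ranked <- rank_and_cumulate(
    filter_clusters(build_clusters(idx), 1, 1),
    n_sequences = 15, decimals = 10)
  dedup <- deduplicate_by_cumulative(ranked)
  coverable <- recs$seq_id[nchar(recs$sequence) >= 20]
  expect_equal(cluster_coverage_union(dedup), coverable)
})

test_that("retained clusters form a valid cover no smaller than the exact optimum", {
  for (seed in 1:10) {
    recs <- synthesize_fasta(5 + seed %% 5, 40, mode = "family",
                             n_ancestors = 2, substitution_rate = 0.03,
                             seed = 300 + seed)
    idx <- enumerate_candidates(recs, 14)
    ranked <- rank_and_cumulate(
      filter_clusters(build_clusters(idx), 1, 1),
      n_sequences = nrow(recs), decimals = 4)
    dedup <- deduplicate_by_cumulative(ranked)
    coverable <- index_universe(idx)
    expect_equal(cluster_coverage_union(dedup), coverable)
    # the exhaustive oracle runs over every filtered cluster (its stated
    # precondition caps the family count; instances are sized to respect it)
    expect_lte(length(ranked$seq_ids), 20)
    opt <- exact_min_cover(coverable, ranked$seq_ids)
    expect_gte(nrow(dedup), opt)
  }
})
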