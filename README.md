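# oligocover

Near-optimal multiplex primer and probe panel design by set-cover
approximation.

## The problem

Multiplex assays — multiplex PCR, digital multiplex ligation assays,
hybridisation probe panels — need a *small* set of ~20 nt oligonucleotides
that together recognise a *large and heterogeneous* collection of target DNA
sequences (viral genomes, resistance-gene variants, strain collections).
Formally this is a minimum set-cover problem: choose the fewest primers such
that every input sequence contains at least one of them as an exact
substring. Set cover is NP-hard, so exact solutions do not scale to the
thousands of sequences a surveillance panel must handle. `oligocover` is for
molecular diagnostics and microbiology workers who need that selection to be
automatic, reproducible, and fast on large FASTA inputs.

## The method

For an input of *n* sequences and primer length *k* (default 20):

1. **Candidate enumeration.** Every length-*k* window of every sequence is a
   primer candidate; each distinct k-mer *p* is indexed by its *coverage*
   C(p) ⊆ {1..n}, the set of sequences containing it. Windows containing
   non-A/C/G/T letters are skipped. The window count is exactly
   Σᵢ max(0, Lᵢ − k + 1), so the work grows linearly in total bases.
2. **Optional GC screens.** Candidates with GC fraction outside
   [gc_min, gc_max], or with a GC difference between their two halves above
   `max_gc_half_diff` (useful when a k-mer represents two adjacent probes),
   are removed.
3. **Clustering.** Candidates are partitioned by exact equality of coverage
   sets. Each *primer cluster* is a maximal group of k-mers with identical
   coverage; its shared coverage set is the *sequence group*. Any single
   primer from a cluster covers the whole group, so clusters become the
   units of the cover.
4. **Filtering, ranking, cumulative coverage.** Clusters below the
   user cut-offs on primer-group and sequence-group size are dropped. The
   rest are ordered by sequence-group size (then primer-group size, then a
   lexicographic tie-break), and a running union of sequence groups gives
   each cluster a cumulative coverage |U₁..ᵣ|/n, rounded to *d* decimals.
5. **Deduplication.** Clusters sharing a rounded cumulative value added
   nothing distinguishable at that precision; within each such group only
   the clusters of maximal sequence-group (then primer-group) size are
   kept. Coarser rounding (smaller *d*) prunes more aggressively.

The retained, ranked clusters are a near-optimal cover: every coverable
sequence is covered when the cut-offs are 1, and picking one primer per
cluster yields the panel.

## Worked example

```r
library(oligocover)

# three simulated gene families, four members each, 2% divergence
recs <- synthesize_fasta(n_sequences = 12, bases_per_sequence = 150,
                         mode = "family", n_ancestors = 3,
                         substitution_rate = 0.02, seed = 42)
res <- design_primers(recs, min_sequence_group_size = 1)
res
#> <oligocover_result>
#>   sequences: 12 (1800 bases)
#>   primer clusters: 3 (57 candidate primers)
#>   excluded sequences: 0
#>   final cumulative coverage: 1
#>   primer length k = 20

primers(res)[, c("cluster_id", "seq_ids", "primer_group_size",
                 "sequence_group_size", "cumulative_coverage")]
#> # A tibble: 3 × 5
#>   cluster_id seq_ids  primer_group_size sequence_group_size cumulative_coverage
#>        <int> <chr>                <int>               <int>               <dbl>
#> 1          1 3,6,9,12                35                   4               0.333
#> 2          2 1,4,7,10                15                   4               0.667
#> 3          3 2,5,8,11                 7                   4               1
```

The method recovered the three families exactly: each cluster's sequence
group is one family (e.g. sequences 3, 6, 9, 12 are the copies of ancestor
3), and any one of its interchangeable primers (35, 15 and 7 of them
respectively) detects all four members. Cumulative coverage climbs to 1, so
three oligonucleotides suffice for all twelve targets. `autoplot(res)`
draws the cluster × sequence coverage heatmap (dark = covered);
`sequences(res)` gives the per-sequence transpose view, and
`glance(res)`/`tidy(res)` return the summary and cluster tibbles.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/oligocover run input.fasta --out results \
    --min-sequence-group-size 1 --gc-min 0.4 --gc-max 0.6
```

writing `description.txt`, `conversion_table.tsv`, `primer_candidates.tsv`,
`excluded_sequences.tsv`, `primer_matrix.tsv` and `heatmap.png`. `synth`,
`candidates` and `bench` subcommands expose the generator, the raw candidate
index and the scaling harness.

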