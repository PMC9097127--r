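---
title: "Primer panel design by set-cover approximation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primer panel design by set-cover approximation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocover)
```

## The model

`oligocover` treats multiplex primer/probe selection as an instance of
minimum set cover. The universe is the set of input sequences; every
length-$k$ substring (k-mer) of any input is a candidate primer, and the
set it "covers" is the set of sequences containing it exactly. The exact
optimisation is NP-hard, so the package computes a near-optimal cover with
a deterministic, linear-scaling reduction:

1. enumerate all $\sum_i \max(0, L_i - k + 1)$ sliding windows and index
   each distinct k-mer by its coverage set;
2. optionally screen candidates on GC content;
3. partition candidates into **primer clusters** by *identical* coverage
   sets — each cluster's shared coverage is its **sequence group**;
4. drop clusters below the size cut-offs, rank the rest by size, and walk
   the ranking accumulating the union of sequence groups, recording each
   cluster's rounded cumulative coverage;
5. within runs of equal rounded cumulative coverage keep only the
   largest clusters.

The key modelling assumption is **exact substring matching**: a primer
covers a sequence only if it occurs verbatim. No melting temperature,
mismatch tolerance, dimer or specificity model is applied — candidates are
combinatorial objects, and thermodynamic screening is deliberately out of
scope. The coverage semantics also uses the **given strand only**; if
primers may bind either strand, add the reverse complements to the input.

Clustering by *identical* coverage (rather than any transitive linkage of
overlapping coverage sets) is the only reading under which a primer cluster
covers exactly one sequence cluster, which the ranking step relies on; it
also makes the partition property testable by brute-force substring search,
and the test suite does exactly that.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `primer_length` (k) | 20 nt | candidate window length; 20 nt is the conventional primer length, and for adjacent-probe (ligation) designs a 20-mer reads as two abutting 10-mers |
| `min_primer_group_size` | 1 | smallest primer cluster kept; raising it demands redundant (interchangeable) primers per cluster |
| `min_sequence_group_size` | 2 | smallest sequence group kept; the default discards primers private to a single sequence, set 1 to force full coverage of small or diverse inputs |
| `decimals` (d) | 4 | rounding precision of cumulative coverage, the dial of the deduplication: smaller d merges more near-redundant clusters; with $10^{-d} < 1/n$ deduplication provably removes only zero-contribution clusters |
| `gc_min`, `gc_max` | unset | GC-fraction range (proxy for hybridisation stability), applied per candidate |
| `max_gc_half_diff` | unset | cap on the GC difference between the candidate's two halves, for adjacent-probe pairs that should melt comparably |

All parameters used are echoed into the result's `description` element and
`description.txt` for provenance.

## Numerical and procedural choices

* **Rounding** of cumulative coverage is half-away-from-zero (0.125 → 0.13
  at two decimals). Base R's `round()` rounds half to even, which would make
  the deduplication grouping depend on parity; a fixed commercial-rounding
  convention is implemented instead (with a $10^{-9}$ guard against binary
  representation error in ratios of small integers).
* **Ordering** "by size" is sequence-group size descending — coverage is
  the quantity being maximised — with primer-group size descending as the
  secondary key and the lexicographically smallest member primer as a final
  deterministic tie-break, so output order is identical across runs and
  platforms.
* **Cumulative values are frozen** from the pre-deduplication walk, not
  recomputed afterwards: they are computed once and then used as the
  grouping key, and recomputing them would change the groups being
  collapsed mid-flight.
* **Ties within a deduplication group** (equal cumulative value, equal
  sequence-group and primer-group size) are all retained rather than broken
  arbitrarily.
* **Ambiguity codes** (`N`, `R`, `Y`, …) are accepted in input sequences,
  but any window containing one is skipped, not expanded into degenerate
  candidates — expansion would silently change what "covers" means.
  `U` is rejected outright: the tool is specified for DNA.
* **Odd k halves** for the GC-half filter: the first half takes
  $\lceil k/2 \rceil$ bases. Any fixed convention works; this one is
  documented and tested.
* **GC filters run on candidates, before clustering** — the only order in
  which "remove a primer" is well defined, since after clustering a primer
  is no longer an independent unit.
* **Degenerate inputs**: sequences shorter than $k$ are carried through and
  reported as excluded with reason `too_short`; filtering *every* candidate
  out is legal and yields an empty cluster table with all sequences
  excluded (the heatmap then refuses to draw, with an explanatory error).
  Exclusion reasons name the first stage that removed a sequence's last
  coverage (`filtered_gc`, `filtered_cluster_cutoffs`,
  `no_shared_candidate_surviving`); the reason column is an inexpensive
  diagnostic extension and `strict = TRUE` omits it on export.

## The synthetic-data generator

`synthesize_fasta()` produces the two input regimes used throughout the
tests:

* **`uniform_random`** — every base i.i.d. uniform over A/C/G/T. This is
  the regime of the scaling benchmarks (e.g. 300 sequences totalling
  3·10⁴–3·10⁵ bases in the harness runs, mirroring benchmark sets of 300
  sequences and 465 000 bases at 1 550 bp each). Random 20-mers essentially
  never recur across sequences, so this regime exercises throughput and the
  singleton-cluster path, not cluster structure. Sequence lengths are equal
  within a set; the generator takes one seed and never touches the global
  RNG stream.
* **`family`** — ancestors drawn uniformly at random, then copies with
  i.i.d. substitutions at a given per-base rate (default 2%, a typical
  within-species divergence scale). Family members share long exact
  k-mers, so realistic primer clusters emerge; the cluster-soundness and
  cover-validity tests run on 10 ancestors × 10 copies of 200 bp at 2%
  substitution.

What the generator does **not** emulate: indels, recombination, local GC
skew, repeats, length variation and sequencing artefacts. Passing tests
therefore demonstrate the combinatorial machinery is correct, not that a
designed panel will amplify efficiently on real templates — primer
candidates here are exact substrings, and any wet-lab screening
(melting temperature, dimers, specificity) must follow downstream.

## Verification strategy and problem sizes

Every stage is checked against an independent brute-force oracle: a
scalar-loop substring multimap for enumeration (100 seeded fixtures up to
10⁵ bases), per-kmer base recounts for the GC screens (10⁴ random
20-mers), from-scratch union walks for cumulative coverage, substring
search for cluster soundness, and an exhaustive exact set-cover search
(≤ 20 families) confirming on 50 small instances (≤ 12 sequences) that the
retained clusters form a valid cover no smaller than the optimum. Linear
scaling is witnessed deterministically by exact window counts across a 1× to
10× harness (6·10⁴ to 6·10⁵ bases in the suite, 3·10⁴ to 3·10⁵ in the
acceptance script) with a loose smoke bound on wall time, since absolute
timings are hardware-bound. Determinism is enforced by comparing the bytes
of two complete output trees.

## Known limitations

* Exact matching only: one mismatch in a target defeats a primer that
  would still anneal in practice; conversely every exact match is assumed
  usable.
* Single-strand coverage semantics (see above).
* The approximation has no worst-case guarantee tighter than the trivial
  one; on adversarial inputs the retained panel can exceed the optimum,
  though the ranking-by-size heuristic mirrors the classic greedy cover.
* The cluster table returns interchangeable primers per cluster but does
  not choose among them; panel finalisation (one primer per cluster, lab
  constraints) is left to the user.
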