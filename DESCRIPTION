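Package: oligocover
Title: Near-Optimal Multiplex Primer and Probe Panel Design by Set-Cover Approximation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs compact panels of oligonucleotide primers or probes
    against large, heterogeneous DNA sequence sets. Every k-length
    subsequence of the input FASTA is enumerated as a primer candidate,
    candidates are grouped into clusters by identical sequence coverage,
    and the clusters are filtered, ranked and deduplicated to yield a
    near-optimal approximation of the minimal set cover of the input
    sequences. Results are returned as tidy tibbles with a TRUE/FALSE
    coverage matrix and a ggplot2 heatmap, and the whole pipeline scales
    linearly with the number of input bases. Optional GC-content filters
    support adjacent-probe (e.g. ligation assay) designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
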