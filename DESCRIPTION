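Package: methdx
Title: Bisulfite Conversion Diagnostics and Tests for the Presence of CpG
    DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to decide whether a whole-genome bisulfite sequencing
    (WGBS) experiment shows genuine CpG DNA methylation or only
    conversion and sequencing artifacts.  Implements methratio-style
    per-cytosine methylation calling from bisulfite alignments, bisulfite
    conversion-rate estimation, replicate intersection of partially
    unconverted sites, chromosome-placement partitioning, the
    coverage-versus-proportion Spearman diagnostic and a formal
    absent/present/inconclusive verdict; the CpG observed/expected
    depletion signature with a Gaussian-mixture bimodality test; and
    efficiency-corrected relative expression for qPCR (Pfaffl ratios,
    fixed-reallocation randomization test, bootstrap confidence
    intervals, Bonferroni adjustment).  Ships seeded simulators for
    genomes, methylomes, bisulfite reads and pileups and qPCR
    crossing-point tables so every stage is testable against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
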