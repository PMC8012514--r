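Package: crossvar
Title: Single Amino Acid Variant Enumeration and Cross-Species Variant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exhaustive enumeration of non-synonymous single
    nucleotide variants (nsSNVs) from coding sequences, aggregation of
    nucleotide-level variants into single amino acid variants (SAVs) with
    population-frequency strata (synthetic, singleton, rare, common),
    cross-species variant (CSV) calling from human-anchored ortholog
    protein alignments, stratified analysis of variant effect scores and
    per-position conservation, and a resampled two-sample
    Kolmogorov-Smirnov protocol for comparing score distributions.
    Includes a synthetic cohort generator with planted ground truth so
    every pipeline stage can be exercised and validated without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
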