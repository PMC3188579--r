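Package: seqdge
Title: Modular RNA-Seq Differential Expression Pipeline with an Exact
    Negative-Binomial-Power Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully testable RNA-Seq differential expression
    pipeline: a reference catalog built from FASTA and GFF3 annotation
    (including synthetic splice-junction sequences), read preprocessing and
    collapsing to unique sequences with per-replicate occurrence counts,
    an exhaustive 2-bit hashed-seed short-read aligner with SAM input and
    output, rule-based gene and isoform counting, replicate quality
    assessment via intraclass correlation coefficients, an exact two-group
    test under a negative binomial model whose dispersion depends on the
    mean (the NBP model) with random-thinning normalization and Storey
    q-values, gene ontology term enrichment (term-for-term, parent-child,
    permutation), and a seeded synthetic-data generator so every stage is
    exercisable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
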