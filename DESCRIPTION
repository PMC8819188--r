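Package: pseudex
Title: Characterisation and Classification of Pseudoexon-Activating Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for cataloguing pseudoexons (cryptic exons) and the
    deep-intronic mutations that activate them. Provides HGVS-style cDNA
    variant parsing with intronic offsets and strand-aware genomic mapping,
    splice-site log-odds motif scoring under pluggable models (including
    loaders for published maximum-entropy table layouts), AG-exclusion-zone
    and branch-point analysis with the "close the circuit" rule, hexamer
    enhancer/silencer delta scoring, a rule-based taxonomy of instigating
    mutations with an evidence trail, transcript-level consequence annotation
    (reading frame, premature termination, nonsense-mediated decay, poison
    and novel exon candidacy, terminal pseudoexons), overlap of pseudoexon
    splice sites with recursive-splice-site coordinate sets, catalogue
    summary statistics, and a fully seeded synthetic-locus generator so that
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
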