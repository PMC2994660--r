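Package: coevoscan
Title: Codon-Model Selection Scans and Hybrid-Genome ChIP Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum-likelihood codon substitution models for detecting
    selection on protein-coding genes, and a windowed ChIP-Seq enrichment
    pipeline for hybrid genomes. Implements the Goldman-Yang codon rate
    matrix with F3x4 frequencies, Felsenstein pruning likelihoods, the
    single-ratio (M0), beta site-mixture (M7), beta-plus-selection (M8) and
    free-ratio branch models, the M7-vs-M8 likelihood-ratio test with Bayes
    Empirical Bayes per-codon posteriors, sliding-window dN/dS scans with an
    empirical genome-window null distribution, length-weighted ortholog
    percent-identity summaries, and IP/Input window-median enrichment ratios
    for ChIP-Seq over concatenated two-species genomes. Includes seeded
    simulators for codon alignments evolved under each model and for
    coverage tracks with planted fold enrichment, so every stage can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
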