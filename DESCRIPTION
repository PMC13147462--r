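Package: indelrate
Title: Length-Stratified Germline INDEL Mutation Rate Maps from Long Sequence Context
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A breakpoint-centric framework for estimating germline short
    insertion/deletion (INDEL) mutation rates from long sequence context.
    Population variants are downsampled to rare-variant proxies of de novo
    mutations (hypergeometric allele-count thinning, enumeration-based
    realignment, coverage and exon filtering), decomposed into insertion,
    deletion-start and deletion-end breakpoints with length classes, and used
    to train a one-dimensional U-Net that maps a one-hot encoded context
    window to a per-junction probability vector over INDEL length classes.
    Raw probabilities are refined by Dirichlet calibration, a Poisson
    recurrence correction and genome-rate scaling; deep-ensemble mutual
    information quantifies epistemic uncertainty. Evaluation includes k-mer
    and regional observed/predicted rate correlations, depletion-rank
    constraint scores, meta-gene rate profiles, and gradient-based
    interpretability (integrated gradients, seqlet extraction, PWM/CWM motif
    construction and filtering). A seeded synthetic-data module generates
    genomes, true rate maps and population cohorts so the full pipeline is
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
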