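Package: cghcnv
Title: Consensus Copy-Number Variant Discovery and cis-eQTL Mapping from
    Tiling aCGH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for population-scale copy-number
    variation (CNV) analysis on high-density tiling array comparative
    genomic hybridization (aCGH) data. Per-sample log2-ratios are
    normalized for probe GC-content bias and chromosomal wave artifacts
    with signal-to-noise guided selection of the wave-correction span.
    CNV segments are called by three algorithmically independent
    segmentation methods (a penalized piecewise-constant fit, a recursive
    arc-based binary segmentation with permutation testing, and a sliding
    window scan with Bayesian carrier probabilities); high-confidence
    calls are retained by a two-of-three consensus rule, merged across
    individuals into copy-number variable regions (CNVRs), genotyped
    quantitatively as median log2-ratios, and analysed for population
    structure. CNVR genotypes are then associated with proximal gene
    expression (cis-eQTL) per tissue with a principal-component
    covariate, gene-level permutation correction, Storey q-value FDR
    control, and a region-level secondary association scan. A synthetic
    data module simulates probe sets, CNV landscapes, arrays and
    multi-tissue expression with known ground truth so every stage is
    testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    ape,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    withr
Config/testthat/edition: 3
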