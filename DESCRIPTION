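Package: pairmet
Title: Comparative Exome Analysis of Paired Tumor Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing somatic alterations between anatomically
    distinct metastases sequenced together with a matched normal sample.
    Implements Bayesian most-probable-genotype (MPG) calling from pileup
    evidence, a somatic filtering cascade (common-variant panel, quality
    gates, tumor/normal subtraction, zygosity and coding-effect
    annotation), metastasis-versus-metastasis mutation concordance tables,
    six-class mutation spectra with a UV dinucleotide signature scan,
    read-count pseudo-CGH copy-number profiling with circular binary
    segmentation and derivative log-ratio spread calibration,
    loss-of-heterozygosity binning with copy-neutral LOH flagging, and
    hypergeometric gene-set over-representation with Benjamini-Hochberg
    control. A synthetic-data generator produces matched
    normal/metastasis trios with known ground truth so the whole pipeline
    is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
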