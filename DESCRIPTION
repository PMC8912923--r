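Package: socewas
Title: Season-of-Conception Cosinor EWAS, Matched Controls, Enrichment and
    mQTL Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects seasonal (conception-date) effects on DNA methylation
    with per-CpG Fourier (cosinor) regression on M-values, including
    per-CpG outlier masking, likelihood-ratio testing, Benjamini-Hochberg
    FDR, seasonal amplitude and peak-day estimation, and a genomic
    inflation factor. Downstream tools select hit CpGs by FDR and
    amplitude, construct distribution-matched and random control sets,
    quantify cross-dataset replication and attenuation, cluster CpGs by
    genomic distance with cluster-aware annotation enrichment and
    bootstrapped proximity curves, classify gametic methylation status,
    and map cis/trans methylation quantitative trait loci with variance
    decomposition, gene-by-season interaction scans and genotype-season
    association checks. A synthetic-cohort generator with known truth
    supports power analysis and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
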