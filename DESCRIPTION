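Package: admixscan
Title: f-Statistics, qpAdm-Style Mixture Models and Admixture-Graph
    Inference for Bovid Population Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring admixture history from genome-wide allele
    frequency data, built around the f-statistic framework: unbiased f2/f3/f4
    estimators with weighted 5-cM block-jackknife standard errors, qpAdm-style
    estimation of mixture proportions (including the restricted-reference
    "ghost lineage" estimator for contributions from unsampled basal
    branches), admixture-graph fitting by generalized least squares on the f2
    basis with block-bootstrap out-of-bag model comparison, a coalescent
    simulation harness encoding explicit cattle/aurochs demographies for
    false-positive/false-negative calibration of introgression signals, and a
    windowed f2 scan that localizes minor-ancestry segments by outgroup f4
    enrichment in the most model-divergent bins. Includes EIGENSTRAT
    genotype input/output with pseudo-haploid support and fast synthetic-data
    generators (drift along an admixture graph; segment-mosaic genomes).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: python3 with msprime (coalescent simulation only)
RoxygenNote: 7.3.3
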