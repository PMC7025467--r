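Package: admixkit
Title: Admixture Graph Inference and f-Statistics for SNP Allele Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring population trees with migration events from
    biallelic SNP allele frequencies under the Gaussian drift approximation:
    genotype and TreeMix-format frequency I/O, quality-control filters,
    within-species linkage-disequilibrium decay and SNP block-size
    determination, an allele-frequency covariance engine with block-jackknife
    standard errors, maximum composite-likelihood tree search with sequential
    migration-edge fitting, f3/f4 admixture statistics with weighted block
    jackknife and Holm-Bonferroni control, Robinson-Foulds/strict-consensus
    tree post-processing, block-bootstrap migration-support indices, and a
    synthetic admixture-graph data simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    ape,
    phangorn,
    pracma,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
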