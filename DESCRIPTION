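Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and Selection-Signature
    Scans for SNP-Array Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for breed-level analysis of medium-density SNP-array
    genotypes: PLINK text and binary input/output, per-branch quality
    control (call rate, minor allele frequency, exact Hardy-Weinberg
    test, genomic-relationship based duplicate removal, linkage
    disequilibrium pruning), sliding-window detection of runs of
    homozygosity (ROH) with a genome-wide L parameter, genomic inbreeding
    coefficients (F_ROH) overall and by length class, ROH-island calling
    from z-scored ROH incidence, per-locus Weir-Cockerham FST scans with
    empirical outlier thresholds, observed-heterozygosity diversity
    summaries, and candidate-gene annotation within a configurable flank.
    A multi-population cohort simulator with Balding-Nichols divergence
    and planted autozygous tracts, island loci and outlier loci provides
    known truth for every stage, and a config-driven pipeline runs the
    whole analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
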