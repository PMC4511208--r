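Package: snpdrift
Title: Tests for Negative Selection at Candidate SNPs from Sparse Multi-Cohort Genotypes
Version: 0.1.0
Authors@R:
    person("Kiang", "West", email = "maintainer@snpdrift.org", role = c("aut", "cre"))
Description: Detects negative selection at a small candidate SNP set from
    sparsely genotyped, unlinked markers in three population cohorts. Implements
    two complementary tests: an exhaustive 3-SNP-subset empirical-null test on
    cross-cohort minor-allele-frequency changes (unadjusted and Welch-variance-
    adjusted), and a Balding-Nichols beta-binomial drift model with grid maximum
    likelihood estimation of per-population drift and conditional tail
    probabilities for the target cohort. Includes the SNP filtering cascades
    (call rate, monomorphic, LD pruning) both tests require, a synthetic
    three-cohort genotype generator for fixtures and calibration, tabular and
    VCF genotype I/O, and an end-to-end pipeline with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    yaml,
    optparse
Config/testthat/edition: 3
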