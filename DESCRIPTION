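Package: cardiogwas
Title: GWAS Pipeline for Nested Case-Control Studies of Myocardial Infarction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for two-cohort nested case-control
    genome-wide association analysis of myocardial infarction and blood
    biomarkers: genotype and sample quality control with genomic control,
    per-SNP additive logistic and linear association scans, fixed-effects
    inverse-variance and sample-size-weighted signed-z meta-analysis, SNP-set
    enrichment analysis of eSNP sets via Kolmogorov-Smirnov tests, a
    four-model gene-by-environment interaction screen based on nested
    likelihood-ratio tests, and unweighted allele-count genotype risk scores
    with distance-based LD pruning. Includes a synthetic two-cohort study
    generator so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    fgsea,
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
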