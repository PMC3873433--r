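#!/usr/bin/env Rscript
# Aggregate genotype risk scores: derive score alleles from one cohort's
# biomarker (and MI) associations, score the other cohort's subjects, and
# sweep the score size N.

source(file.path("analysis", "common.R"))

st <- get_study()
scans <- get_scans(st)

derive <- scans[[1]]                       # derivation cohort
eval_co <- st$cohorts[[2]]                 # evaluation cohort
eval_ph <- eval_co$phenotypes

sweep <- sweep_thresholds(
  derive[c("ldl", "hdl", "apob", "tg", "adiponectin", "crp", "tc", "mi")],
  n_grid = c(10, 50, 100, 500),
  gm = eval_co$genotypes, status = eval_ph$status,
  trait_sets = list("ldl", "hdl", "mi",
                    c("ldl", "hdl", "apob", "tg", "adiponectin", "crp",
                      "tc"),
                    c("ldl", "hdl", "apob", "tg", "adiponectin", "crp",
                      "tc", "mi")))
write_result(sweep, "07_riskscore_sweep.tsv")

biomarker_mi <- sweep[sweep$trait_set ==
                        "ldl+hdl+apob+tg+adiponectin+crp+tc+mi", ]
message(sprintf(
  "Cross-cohort biomarker+MI score: p = %s across N = {10, 50, 100, 500}.",
  paste(signif(biomarker_mi$p, 2), collapse = ", ")))
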