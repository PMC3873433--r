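# Shared setup for the numbered analysis scripts. The study is simulated
# deterministically from one seed, so every script can rebuild the same
# data instead of passing large intermediates around; a cache under
# scratch/ (not part of the deliverable) avoids recomputation.

library(cardiogwas)

RESULTS_DIR <- file.path("results")
SCRATCH_DIR <- file.path("scratch", "analysis_cache")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(SCRATCH_DIR, showWarnings = FALSE, recursive = TRUE)

study_config <- function() {
  # Emulated design: cohort sizes of the two nested case-control studies,
  # 2,000 SNPs in 10-SNP LD blocks, 20 disease-causal SNPs at OR 1.4,
  # biomarker effects 0.25 SD/allele, 100 gene sets (3 enriched), two
  # pure-interaction SNPs.
  sim_config(seed = 42)
}

get_study <- function() {
  cache <- file.path(SCRATCH_DIR, "study.rds")
  if (file.exists(cache)) return(readRDS(cache))
  st <- simulate_study(study_config(), cohort_labels = c("nhs_like",
                                                         "hpfs_like"))
  saveRDS(st, cache)
  st
}

get_qc <- function(study = get_study()) {
  cache <- file.path(SCRATCH_DIR, "qc.rds")
  if (file.exists(cache)) return(readRDS(cache))
  qc <- lapply(study$cohorts, function(co) {
    apply_qc(co$genotypes, check_duplicates = FALSE)
  })
  saveRDS(qc, cache)
  qc
}

covariate_matrix <- function(pheno, cols = c("age", "smoke", "pc1", "pc2")) {
  as.matrix(pheno[, cols])
}

get_scans <- function(study = get_study(), qc = get_qc(study)) {
  cache <- file.path(SCRATCH_DIR, "scans.rds")
  if (file.exists(cache)) return(readRDS(cache))
  traits <- c("ldl", "hdl", "apob", "tg", "adiponectin", "crp", "tc")
  scans <- lapply(names(study$cohorts), function(nm) {
    co <- study$cohorts[[nm]]
    gm <- qc[[nm]]$genotypes
    ph <- co$phenotypes[match(rownames(gm$calls), co$phenotypes$sample_id), ]
    cv <- covariate_matrix(ph)
    out <- list(mi = logistic_scan(gm, ph$status, covariates = cv,
                                   trait = "mi", cohort = nm))
    for (tr in traits) {
      out[[tr]] <- linear_scan(gm, ph[[tr]], covariates = cv, trait = tr,
                               cohort = nm)
    }
    out
  })
  names(scans) <- names(study$cohorts)
  saveRDS(scans, cache)
  scans
}

get_meta <- function(study = get_study()) {
  scans <- get_scans(study)
  cache <- file.path(SCRATCH_DIR, "meta.rds")
  if (file.exists(cache)) return(readRDS(cache))
  meta <- lapply(names(scans[[1]]), function(tr) {
    meta_scan(scans[[1]][[tr]], scans[[2]][[tr]])
  })
  names(meta) <- names(scans[[1]])
  saveRDS(meta, cache)
  meta
}

write_result <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
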