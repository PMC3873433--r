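# Genotype and sample quality control: the array-era filter set
# (monomorphic, call rate, HWE, MAF), duplicate detection by genotype
# concordance, PCA ancestry screening, and genomic control.

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of the observed genotype counts
#' against the proportions expected at the observed allele frequency. No
#' continuity correction. A monomorphic SNP returns p = 1 (departure from
#' HWE is undefined there; monomorphism is handled by its own filter).
#'
#' @param counts Integer vector `(n_AA, n_Aa, n_aa)` of genotype counts.
#' @return Two-sided p-value from `chisq(1)`.
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  x2 <- sum((counts - expected)^2 / expected)
  stats::pchisq(x2, df = 1, lower.tail = FALSE)
}

#' Per-SNP quality-control filters
#'
#' Flags each SNP with every failing rule (rules are not short-circuited):
#' monomorphic, missing call rate at or above `max_missing`, HWE p below
#' `hwe_p_min`, minor allele frequency below `maf_min`.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Exclude when missing rate `>=` this value.
#' @param hwe_p_min Exclude when the HWE p-value is `<` this value.
#' @param maf_min Exclude when MAF `<` this value.
#' @return Data frame (one row per SNP): `snp_id`, `call_rate`, `maf`,
#'   `hwe_p`, `kept`, `fail_reasons` (comma-joined, empty when kept).
#' @export
snp_filters <- function(gm, max_missing = 0.02, hwe_p_min = 1e-4,
                        maf_min = 0.02) {
  stopifnot(inherits(gm, "genotype_matrix"), ncol(gm$calls) > 0)
  calls <- gm$calls
  call_rate <- 1 - colMeans(is.na(calls))
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  p_alt <- (2 * n2 + n1) / (2 * pmax(n0 + n1 + n2, 1L))
  snp_maf <- pmin(p_alt, 1 - p_alt)
  hwe_p <- vapply(seq_len(ncol(calls)), function(j) {
    if (n0[j] + n1[j] + n2[j] == 0) return(NA_real_)
    hwe_test(c(n0[j], n1[j], n2[j]))
  }, numeric(1))
  mono <- snp_maf == 0
  reasons <- mapply(function(m, cr, hp, mf) {
    r <- character(0)
    if (m) r <- c(r, "monomorphic")
    if (1 - cr >= max_missing) r <- c(r, "call_rate")
    if (!m && !is.na(hp) && hp < hwe_p_min) r <- c(r, "hwe")
    if (!m && mf < maf_min) r <- c(r, "maf")
    paste(r, collapse = ",")
  }, mono, call_rate, hwe_p, snp_maf)
  data.frame(snp_id = gm$snp_meta$id, call_rate = call_rate, maf = snp_maf,
             hwe_p = hwe_p, kept = !nzchar(reasons), fail_reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Per-sample quality-control filters
#'
#' Flags samples with call rate below `min_call_rate` and, among pairs whose
#' genotype concordance over the non-missing overlap exceeds
#' `dup_concordance` (a proxy for identity-by-descent duplicates), the member
#' with the lower call rate.
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate Exclude when call rate `<` this value.
#' @param dup_concordance Pairwise concordance above which a pair is treated
#'   as an accidental duplicate.
#' @param check_duplicates Set `FALSE` to skip the O(n^2) duplicate sweep.
#' @return Data frame: `sample_id`, `call_rate`, `kept`, `fail_reasons`.
#' @export
sample_filters <- function(gm, min_call_rate = 0.98, dup_concordance = 0.95,
                           check_duplicates = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$calls) > 0)
  calls <- gm$calls
  call_rate <- 1 - rowMeans(is.na(calls))
  reasons <- ifelse(call_rate < min_call_rate, "call_rate", "")
  if (check_duplicates && nrow(calls) > 1) {
    flag <- duplicate_flags(calls, call_rate, dup_concordance)
    reasons <- ifelse(flag,
                      ifelse(nzchar(reasons),
                             paste(reasons, "duplicate", sep = ","),
                             "duplicate"),
                      reasons)
  }
  data.frame(sample_id = rownames(calls), call_rate = call_rate,
             kept = !nzchar(reasons), fail_reasons = reasons,
             stringsAsFactors = FALSE)
}

# Concordance via genotype-indicator cross-products: for each genotype value
# g, I_g %*% t(I_g) counts matching non-missing pairs; dividing by the
# non-missing overlap gives pairwise concordance without an explicit loop.
duplicate_flags <- function(calls, call_rate, threshold) {
  n <- nrow(calls)
  obs <- !is.na(calls) * 1
  overlap <- obs %*% t(obs)
  match_ct <- matrix(0, n, n)
  for (g in 0:2) {
    ig <- (!is.na(calls) & calls == g) * 1
    match_ct <- match_ct + ig %*% t(ig)
  }
  conc <- match_ct / pmax(overlap, 1)
  conc[overlap == 0] <- 0
  flag <- logical(n)
  pairs <- which(upper.tri(conc) & conc > threshold, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    drop_idx <- if (call_rate[i] < call_rate[j]) i
                else if (call_rate[j] < call_rate[i]) j
                else max(i, j)   # tie: drop the later sample
    flag[drop_idx] <- TRUE
  }
  flag
}

#' Thin SNPs by physical distance
#'
#' Keeps, per chromosome, a subset of SNPs pairwise at least `min_distance`
#' apart (greedy left-to-right sweep). Intended to supply a low-LD SNP
#' subset to [pca_ancestry()].
#'
#' @param snp_meta Data frame with `id`, `chrom`, `pos`.
#' @param min_distance Minimum pairwise distance in base pairs.
#' @return Character vector of kept SNP ids.
#' @export
thin_by_distance <- function(snp_meta, min_distance = 100000) {
  kept <- character(0)
  for (ch in unique(snp_meta$chrom)) {
    sub <- snp_meta[snp_meta$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    last <- -Inf
    for (i in seq_len(nrow(sub))) {
      if (sub$pos[i] - last >= min_distance) {
        kept <- c(kept, sub$id[i])
        last <- sub$pos[i]
      }
    }
  }
  kept
}

#' PCA-based ancestry screening
#'
#' Mean-imputes missing genotypes per SNP, standardizes each SNP by
#' `sqrt(2 p (1 - p))`, extracts the top principal components, and flags
#' samples farther than `sd_threshold` standard deviations from the mean on
#' component 1 or 2. The caller should supply a low-LD SNP subset (see
#' [thin_by_distance()]).
#'
#' @param gm A [genotype_matrix()].
#' @param n_components Number of components to return (>= 2).
#' @param sd_threshold Flagging threshold in SD units (`Inf` disables).
#' @return List: `keep` (logical per sample), `scores` (samples x
#'   components), `center_sd` (per-component SD used).
#' @export
pca_ancestry <- function(gm, n_components = 2, sd_threshold = 3) {
  stopifnot(inherits(gm, "genotype_matrix"))
  x <- gm$calls
  if (nrow(x) < n_components) stop("fewer samples than components")
  p <- colMeans(x, na.rm = TRUE) / 2
  keep_snp <- !is.na(p) & p > 0 & p < 1
  x <- x[, keep_snp, drop = FALSE]
  p <- p[keep_snp]
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) {
    m <- is.na(x[, j])
    if (any(m)) x[m, j] <- 2 * p[j]
  }
  x <- sweep(x, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  sds <- apply(scores[, 1:2, drop = FALSE], 2, stats::sd)
  mus <- colMeans(scores[, 1:2, drop = FALSE])
  dev <- abs(sweep(scores[, 1:2, drop = FALSE], 2, mus))
  dev <- sweep(dev, 2, sds, "/")
  keep <- if (is.infinite(sd_threshold)) rep(TRUE, nrow(scores))
          else apply(dev <= sd_threshold, 1, all)
  list(keep = keep, scores = scores, center_sd = sds)
}

# median of chisq(1)
CHISQ1_MEDIAN <- 0.4549364

#' Genomic-control inflation factor
#'
#' `lambda = median(z^2) / 0.4549364` (the chi-square(1) median).
#'
#' @param z Vector of signed association z-scores.
#' @return `lambda_gc`.
#' @export
genomic_control <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) == 0) stop("no z-scores supplied")
  if (length(z) < 100) {
    warning("genomic control estimated from fewer than 100 z-scores")
  }
  stats::median(z^2) / CHISQ1_MEDIAN
}

#' Adjust z-scores by genomic control
#'
#' Divides by `sqrt(lambda)`, floored at 1: deflation (`lambda < 1`) is never
#' applied, so the adjustment cannot inflate evidence. Monotone and
#' sign-preserving.
#'
#' @param z Signed z-scores.
#' @param lambda_gc Inflation factor from [genomic_control()].
#' @return Adjusted z-scores.
#' @export
gc_adjust <- function(z, lambda_gc) {
  stopifnot(lambda_gc >= 0)
  z / sqrt(max(lambda_gc, 1))
}

#' Apply SNP and sample filters, returning the filtered matrix
#'
#' Convenience wrapper: runs [sample_filters()] then [snp_filters()] on the
#' retained samples and subsets the matrix to the kept set.
#'
#' @param gm A [genotype_matrix()].
#' @param ... Threshold arguments passed to the two filter functions.
#' @return List: `genotypes` (filtered), `snp_report`, `sample_report`.
#' @export
apply_qc <- function(gm, ...) {
  args <- list(...)
  samp_args <- args[names(args) %in%
                      c("min_call_rate", "dup_concordance", "check_duplicates")]
  snp_args <- args[names(args) %in% c("max_missing", "hwe_p_min", "maf_min")]
  sr <- do.call(sample_filters, c(list(gm), samp_args))
  gm2 <- subset_genotypes(gm, samples = sr$kept)
  pr <- do.call(snp_filters, c(list(gm2), snp_args))
  list(genotypes = subset_genotypes(gm2, snps = which(pr$kept)),
       snp_report = pr, sample_report = sr)
}
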