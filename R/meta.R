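# Two-cohort meta-analysis: fixed-effects inverse-variance combination of
# per-allele effects, and the sample-size-weighted signed-z method in which
# each cohort's signed z-score receives weight sqrt(n_i / sum(n)) so the
# squared weights sum to one.

#' Fixed-effects inverse-variance meta-analysis of two results
#'
#' `effect_meta = sum(effect_i / se_i^2) / sum(1 / se_i^2)`,
#' `se_meta = 1 / sqrt(sum(1 / se_i^2))`. Both results must refer to the
#' same SNP and counted allele; see [harmonize_alleles()].
#'
#' @param r1,r2 Single-row association records (lists or one-row data frames)
#'   with `snp_id`, `reference_allele`, `effect`, `se`.
#' @return List: `snp_id`, `effect_meta`, `se_meta`, `z_meta`, `p_meta`.
#' @export
inverse_variance_meta <- function(r1, r2) {
  if (r1$snp_id != r2$snp_id) stop("mismatched SNP ids")
  if (!identical(as.character(r1$reference_allele),
                 as.character(r2$reference_allele))) {
    stop("unharmonized alleles for ", r1$snp_id,
         "; call harmonize_alleles() first")
  }
  w1 <- 1 / r1$se^2
  w2 <- 1 / r2$se^2
  effect <- (r1$effect * w1 + r2$effect * w2) / (w1 + w2)
  se <- 1 / sqrt(w1 + w2)
  z <- effect / se
  list(snp_id = r1$snp_id, effect_meta = effect, se_meta = se, z_meta = z,
       p_meta = 2 * stats::pnorm(-abs(z)))
}

#' Sample-size-weighted signed-z meta-analysis
#'
#' Combines two cohorts' signed z-scores with weights
#' `w_i = sqrt(n_i / (n_1 + n_2))`, so the squared weights sum to 1:
#' `Z = w_1 z_1 + w_2 z_2`, with `Z ~ N(0, 1)` under the null. The signs of
#' `z_1`, `z_2` must refer to the same counted allele.
#'
#' @param z1,z2 Signed per-cohort z-scores.
#' @param n1,n2 Effective per-cohort sample sizes (> 0).
#' @return List: `z_meta`, `p_meta`, `w1`, `w2`, `n1`, `n2`.
#' @export
sample_size_z_meta <- function(z1, n1, z2, n2) {
  if (any(c(n1, n2) <= 0)) stop("sample sizes must be positive")
  w1 <- sqrt(n1 / (n1 + n2))
  w2 <- sqrt(n2 / (n1 + n2))
  z <- w1 * z1 + w2 * z2
  list(z_meta = z, p_meta = 2 * stats::pnorm(-abs(z)),
       w1 = w1, w2 = w2, n1 = n1, n2 = n2)
}

#' Effective sample size of a case-control cohort
#'
#' Either the total analyzed count (default convention) or
#' `4 / (1/n_cases + 1/n_controls)`, the equivalent balanced-design size.
#'
#' @param n_cases,n_controls Counts.
#' @param convention `"total"` or `"balanced"`.
#' @return Effective n.
#' @export
effective_n <- function(n_cases, n_controls,
                        convention = c("total", "balanced")) {
  convention <- match.arg(convention)
  if (convention == "total") n_cases + n_controls
  else 4 / (1 / n_cases + 1 / n_controls)
}

#' Harmonize the counted allele of a second cohort's results
#'
#' Where cohort 2 counted the other allele of the same SNP (ref/alt swap),
#' flips the allele label and negates `effect` and `z`. Strand flips are not
#' attempted.
#'
#' @param r1,r2 Association data frames from the same scan run on two
#'   cohorts, keyed by `snp_id`.
#' @return `r2` with swapped-allele rows negated and relabelled.
#' @export
harmonize_alleles <- function(r1, r2) {
  m <- match(r2$snp_id, r1$snp_id)
  swap <- !is.na(m) & r2$reference_allele != r1$reference_allele[m]
  if (any(swap)) {
    r2$effect[swap] <- -r2$effect[swap]
    r2$z[swap] <- -r2$z[swap]
    r2$reference_allele[swap] <- r1$reference_allele[m][swap]
  }
  r2
}

#' Meta-analyze two cohorts' association tables
#'
#' Joins on `snp_id` (and `trait` when present), harmonizes alleles, and
#' applies both combination methods to every shared SNP.
#'
#' @param r1,r2 Association data frames from [logistic_scan()] or
#'   [linear_scan()].
#' @param n1,n2 Effective cohort sizes for the signed-z method; default the
#'   per-row `n_used`.
#' @return Data frame: `snp_id`, `trait`, `chrom`, `pos`, `z1`, `z2`,
#'   `z_meta`, `p_meta` (signed-z path), `effect_meta`, `se_meta`,
#'   `z_meta_iv`, `p_meta_iv` (inverse-variance path), `n1`, `n2`.
#' @export
meta_scan <- function(r1, r2, n1 = NULL, n2 = NULL) {
  key1 <- if ("trait" %in% names(r1)) paste(r1$snp_id, r1$trait) else r1$snp_id
  key2 <- if ("trait" %in% names(r2)) paste(r2$snp_id, r2$trait) else r2$snp_id
  m <- match(key1, key2)
  keep <- !is.na(m)
  a <- r1[keep, , drop = FALSE]
  b <- r2[m[keep], , drop = FALSE]
  b <- harmonize_alleles(a, b)
  en1 <- if (is.null(n1)) a$n_used else rep_len(n1, nrow(a))
  en2 <- if (is.null(n2)) b$n_used else rep_len(n2, nrow(a))
  w1 <- sqrt(en1 / (en1 + en2))
  w2 <- sqrt(en2 / (en1 + en2))
  z_meta <- w1 * a$z + w2 * b$z
  wiv1 <- 1 / a$se^2
  wiv2 <- 1 / b$se^2
  effect_meta <- (a$effect * wiv1 + b$effect * wiv2) / (wiv1 + wiv2)
  se_meta <- 1 / sqrt(wiv1 + wiv2)
  z_iv <- effect_meta / se_meta
  data.frame(snp_id = a$snp_id,
             trait = if ("trait" %in% names(a)) a$trait else NA_character_,
             chrom = a$chrom, pos = a$pos,
             reference_allele = a$reference_allele,
             z1 = a$z, z2 = b$z,
             z_meta = z_meta, p_meta = 2 * stats::pnorm(-abs(z_meta)),
             effect_meta = effect_meta, se_meta = se_meta,
             z_meta_iv = z_iv, p_meta_iv = 2 * stats::pnorm(-abs(z_iv)),
             n1 = en1, n2 = en2, stringsAsFactors = FALSE)
}
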