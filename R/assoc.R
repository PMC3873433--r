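# Per-SNP association scans under the additive genetic model: maximum-
# likelihood logistic regression for the binary endpoint, OLS for
# quantitative biomarkers. Wald z per SNP; per-SNP complete-case handling
# of missing genotypes; separation/non-convergence reported as flagged
# null rows, never exceptions.

# Check a covariate matrix for rank deficiency, naming the offending column.
check_full_rank <- function(x) {
  if (is.null(x) || ncol(x) == 0) return(invisible(TRUE))
  q <- qr(cbind(1, x))
  if (q$rank < ncol(x) + 1) {
    bad <- q$pivot[(q$rank + 1):(ncol(x) + 1)] - 1L
    bad <- bad[bad >= 1][1]
    nm <- colnames(x)[bad]
    if (is.null(nm) || is.na(nm)) nm <- paste0("V", bad)
    stop("covariate collinearity involving column '", nm, "'")
  }
  invisible(TRUE)
}

# Logistic ML fit returning effect/se for the column of interest (the last
# design column). Separation and non-convergence are flagged, not thrown.
logistic_wald <- function(design, y) {
  fit <- suppressWarnings(
    stats::glm.fit(design, y, family = stats::binomial()))
  p <- ncol(design)
  r <- fit$qr
  flagged <- !fit$converged || fit$boundary
  cov <- try(chol2inv(r$qr[seq_len(p), seq_len(p), drop = FALSE]),
             silent = TRUE)
  if (inherits(cov, "try-error")) {
    return(list(effect = NA_real_, se = NA_real_, flagged = TRUE,
                loglik = NA_real_))
  }
  coef <- fit$coefficients
  se <- sqrt(diag(cov))[order(r$pivot)]
  eff <- coef[p]
  s <- se[p]
  if (is.na(eff) || is.na(s) || abs(eff) > 15 || s > 100) flagged <- TRUE
  list(effect = if (flagged) NA_real_ else eff,
       se = if (flagged) NA_real_ else s,
       flagged = flagged,
       loglik = -fit$deviance / 2)
}

#' Additive logistic association scan
#'
#' Fits, per SNP, a maximum-likelihood logistic regression of case status on
#' allele dosage plus covariates. Samples with a missing genotype are
#' dropped for that SNP only. Non-convergence or complete separation yields
#' a row with `flagged = TRUE` and missing effect/se/p.
#'
#' @param gm A [genotype_matrix()].
#' @param status 0/1 vector aligned to the samples; both classes required.
#' @param covariates Optional numeric matrix/data frame of adjustment
#'   covariates (full rank required).
#' @param trait,cohort Labels carried into the result.
#' @return Data frame, one row per SNP: `snp_id`, `trait`, `cohort`,
#'   `chrom`, `pos`, `reference_allele`, `effect` (log-odds per allele),
#'   `se`, `z`, `p`, `n_used`, `flagged`.
#' @export
logistic_scan <- function(gm, status, covariates = NULL, trait = "mi",
                          cohort = "cohort") {
  stopifnot(inherits(gm, "genotype_matrix"),
            length(status) == nrow(gm$calls))
  if (!all(status %in% c(0, 1))) stop("status must be 0/1")
  if (length(unique(status)) < 2) stop("status has a single class")
  cv <- prep_covariates(covariates)
  check_full_rank(cv)
  n_snps <- ncol(gm$calls)
  out <- empty_assoc(n_snps)
  for (j in seq_len(n_snps)) {
    g <- gm$calls[, j]
    ok <- !is.na(g)
    if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
    y <- status[ok]
    if (length(unique(y)) < 2 || stats::var(g[ok]) == 0) {
      out$flagged[j] <- TRUE
      out$n_used[j] <- sum(ok)
      next
    }
    design <- cbind(1, if (is.null(cv)) NULL else cv[ok, , drop = FALSE],
                    dosage = as.numeric(g[ok]))
    w <- logistic_wald(design, y)
    out$effect[j] <- w$effect
    out$se[j] <- w$se
    out$flagged[j] <- w$flagged
    out$n_used[j] <- length(y)
  }
  finish_assoc(out, gm, trait, cohort)
}

#' Additive linear association scan
#'
#' Per-SNP OLS of a quantitative trait on allele dosage plus covariates,
#' Wald z with a normal reference.
#'
#' @param gm A [genotype_matrix()].
#' @param trait_values Numeric vector aligned to samples; variance > 0.
#' @param covariates Optional adjustment covariates (full rank required).
#' @param trait,cohort Labels carried into the result.
#' @return Data frame with the same columns as [logistic_scan()], `effect`
#'   in trait units per allele.
#' @export
linear_scan <- function(gm, trait_values, covariates = NULL,
                        trait = "trait", cohort = "cohort") {
  stopifnot(inherits(gm, "genotype_matrix"),
            length(trait_values) == nrow(gm$calls))
  if (stats::var(trait_values, na.rm = TRUE) == 0) {
    stop("trait is constant")
  }
  cv <- prep_covariates(covariates)
  check_full_rank(cv)
  n_snps <- ncol(gm$calls)
  out <- empty_assoc(n_snps)
  for (j in seq_len(n_snps)) {
    g <- gm$calls[, j]
    ok <- !is.na(g) & !is.na(trait_values)
    if (!is.null(cv)) ok <- ok & stats::complete.cases(cv)
    if (sum(ok) < 3 || stats::var(g[ok]) == 0) {
      out$flagged[j] <- TRUE
      out$n_used[j] <- sum(ok)
      next
    }
    design <- cbind(1, if (is.null(cv)) NULL else cv[ok, , drop = FALSE],
                    dosage = as.numeric(g[ok]))
    fit <- stats::lm.fit(design, trait_values[ok])
    p <- ncol(design)
    rdf <- length(fit$residuals) - p
    sigma2 <- sum(fit$residuals^2) / rdf
    xtx_inv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    se <- sqrt(sigma2 * diag(xtx_inv))[order(fit$qr$pivot)]
    out$effect[j] <- fit$coefficients[p]
    out$se[j] <- se[p]
    out$n_used[j] <- sum(ok)
    if (is.na(out$effect[j]) || is.na(out$se[j]) || out$se[j] == 0) {
      out$flagged[j] <- TRUE
      out$effect[j] <- NA_real_
      out$se[j] <- NA_real_
    }
  }
  finish_assoc(out, gm, trait, cohort)
}

prep_covariates <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  cv <- as.matrix(covariates)
  storage.mode(cv) <- "double"
  cv
}

empty_assoc <- function(n) {
  data.frame(effect = rep(NA_real_, n), se = NA_real_, n_used = NA_integer_,
             flagged = FALSE)
}

finish_assoc <- function(out, gm, trait, cohort) {
  z <- out$effect / out$se
  data.frame(snp_id = gm$snp_meta$id, trait = trait, cohort = cohort,
             chrom = gm$snp_meta$chrom, pos = gm$snp_meta$pos,
             reference_allele = gm$snp_meta$alt,
             effect = out$effect, se = out$se, z = z,
             p = 2 * stats::pnorm(-abs(z)),
             n_used = out$n_used, flagged = out$flagged,
             stringsAsFactors = FALSE)
}

#' Tier association results by significance
#'
#' Labels each row `genome_wide`, `suggestive` or `none` and sorts by
#' ascending p. Default thresholds: genome-wide 5e-8 (the conventional
#' GWAS threshold), suggestive 5e-6.
#'
#' @param results An association (or meta) result data frame with a `p`
#'   column.
#' @param genome_wide,suggestive Tier thresholds.
#' @return The input sorted ascending by p with a `tier` column.
#' @export
classify_hits <- function(results, genome_wide = 5e-8, suggestive = 5e-6) {
  stopifnot("p" %in% names(results))
  tier <- ifelse(is.na(results$p), "none",
                 ifelse(results$p < genome_wide, "genome_wide",
                        ifelse(results$p < suggestive, "suggestive", "none")))
  results$tier <- tier
  results[order(results$p), , drop = FALSE]
}
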