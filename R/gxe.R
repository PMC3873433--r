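# Gene-by-environment interaction screen for the binary endpoint: nested
# logistic models compared by likelihood-ratio tests under four model sets
# crossing the environment coding (linear vs 3-df natural cubic spline)
# with the hypothesis tested (interaction-only vs joint SNP main +
# interaction, the Kraft-style 2-df screen).

#' Natural cubic spline basis with three degrees of freedom
#'
#' Interior knots at the tertiles of the observed distribution, boundary
#' knots at the min/max, columns centered. Degrees of freedom fixed at 3.
#'
#' @param env Numeric environment values.
#' @param df Basis dimension (default and intended value 3).
#' @return Numeric matrix with `df` centered columns; attributes `knots`
#'   and `boundary` record the knot placement.
#' @export
spline_basis <- function(env, df = 3) {
  if (length(unique(env)) < df + 2) {
    stop("too few distinct environment values for a ", df, "-df spline")
  }
  b <- splines::ns(env, df = df)
  out <- scale(unclass(b), center = TRUE, scale = FALSE)
  attr(out, "knots") <- attr(b, "knots")
  attr(out, "boundary") <- attr(b, "Boundary.knots")
  attr(out, "scaled:center") <- NULL
  out
}

#' Likelihood-ratio test between nested logistic models
#'
#' `statistic = 2 * (loglik_full - loglik_null)`, floored at zero against
#' numerical noise, referred to chi-square with df equal to the parameter
#' count difference. Column names of the null design must be a subset of
#' the full design's.
#'
#' @param full,null Numeric design matrices (including intercept columns),
#'   same rows.
#' @param y 0/1 response.
#' @return List: `statistic`, `df`, `p`, `flagged` (separation or
#'   non-convergence in either fit).
#' @export
lrt_nested <- function(full, null, y) {
  stopifnot(nrow(full) == nrow(null), nrow(full) == length(y))
  if (ncol(null) > ncol(full)) stop("models are not nested")
  if (ncol(null) == ncol(full)) {
    if (!identical(unname(full), unname(null))) stop("models are not nested")
    return(list(statistic = 0, df = 0L, p = 1, flagged = FALSE))
  }
  if (!is.null(colnames(full)) && !is.null(colnames(null)) &&
      !all(colnames(null) %in% colnames(full))) {
    stop("null model terms are not a subset of the full model terms")
  }
  f_full <- suppressWarnings(
    stats::glm.fit(full, y, family = stats::binomial()))
  f_null <- suppressWarnings(
    stats::glm.fit(null, y, family = stats::binomial()))
  flagged <- !f_full$converged || !f_null$converged || f_full$boundary
  stat <- max(0, f_null$deviance - f_full$deviance)
  df <- ncol(full) - ncol(null)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE), flagged = flagged)
}

#' The four interaction model specifications
#'
#' The cross of environment coding (linear, 3-df spline) with the test
#' (interaction-only LRT; joint SNP main-effect + interaction LRT). The
#' mapping of ids 1-4 to cells is configurable via `order`; the default is
#' linear/interaction, linear/joint, spline3/interaction, spline3/joint.
#'
#' @param order Character vector of four `"coding:test"` strings naming the
#'   id-to-cell mapping.
#' @return Data frame: `model_id`, `coding`, `test`, `df`.
#' @export
gxe_model_specs <- function(order = c("linear:interaction_only",
                                      "linear:joint",
                                      "spline3:interaction_only",
                                      "spline3:joint")) {
  parts <- strsplit(order, ":", fixed = TRUE)
  coding <- vapply(parts, `[`, "", 1)
  test <- vapply(parts, `[`, "", 2)
  if (!all(coding %in% c("linear", "spline3")) ||
      !all(test %in% c("interaction_only", "joint")) ||
      length(order) != 4 || anyDuplicated(order)) {
    stop("model specs must be the four distinct coding:test combinations")
  }
  env_df <- ifelse(coding == "linear", 1L, 3L)
  data.frame(model_id = seq_len(4), coding = coding, test = test,
             df = ifelse(test == "interaction_only", env_df, env_df + 1L),
             stringsAsFactors = FALSE)
}

#' Genome-wide SNP-by-environment interaction screen
#'
#' For every SNP, fits the four nested logistic model pairs (adjusting for
#' the supplied covariates) and reports the four LRT p-values side by side,
#' together with the marginal SNP main-effect p-value, flagging rows where
#' any model p-value falls below `threshold` (a conservative Bonferroni
#' level for a four-model genome-wide screen).
#'
#' @param gm A [genotype_matrix()].
#' @param status 0/1 case status.
#' @param env Numeric environment values aligned to samples.
#' @param covariates Optional adjustment covariates (age, smoking,
#'   principal components).
#' @param specs Model specifications from [gxe_model_specs()].
#' @param threshold Genome-wide significance threshold on any model.
#' @return Data frame, one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `p_model1` .. `p_model4`, `lrt1` .. `lrt4`, `main_effect_p`,
#'   `significant_any`, `flagged`.
#' @export
gxe_scan <- function(gm, status, env, covariates = NULL,
                     specs = gxe_model_specs(), threshold = 1e-9) {
  stopifnot(inherits(gm, "genotype_matrix"),
            length(status) == nrow(gm$calls),
            length(env) == nrow(gm$calls))
  if (!all(status %in% c(0, 1))) stop("status must be 0/1")
  if (!setequal(paste(specs$coding, specs$test),
                c("linear interaction_only", "linear joint",
                  "spline3 interaction_only", "spline3 joint"))) {
    stop("invalid model specifications")
  }
  cv <- prep_covariates(covariates)
  check_full_rank(cv)
  ok_base <- !is.na(env) & !is.na(status)
  if (!is.null(cv)) ok_base <- ok_base & stats::complete.cases(cv)
  spl <- spline_basis(env[ok_base], df = 3)
  env_cols <- list(linear = matrix(env[ok_base], ncol = 1,
                                   dimnames = list(NULL, "env")),
                   spline3 = `colnames<-`(spl[, , drop = FALSE],
                                          paste0("env_s", 1:3)))
  base <- matrix(1, sum(ok_base), 1,
                 dimnames = list(NULL, "(Intercept)"))
  if (!is.null(cv)) base <- cbind(base, cv[ok_base, , drop = FALSE])
  y_all <- status[ok_base]
  g_all <- gm$calls[ok_base, , drop = FALSE]

  n_snps <- ncol(g_all)
  p_mat <- matrix(NA_real_, n_snps, 4)
  lrt_mat <- matrix(NA_real_, n_snps, 4)
  main_p <- rep(NA_real_, n_snps)
  flagged <- rep(FALSE, n_snps)
  for (j in seq_len(n_snps)) {
    g <- g_all[, j]
    ok <- !is.na(g)
    y <- y_all[ok]
    if (length(unique(y)) < 2 || stats::var(g[ok]) == 0) {
      flagged[j] <- TRUE
      next
    }
    gd <- as.numeric(g[ok])
    b <- base[ok, , drop = FALSE]
    # marginal main effect (covariate-adjusted, no environment term)
    w <- logistic_wald(cbind(b, dosage = gd), y)
    main_p[j] <- if (w$flagged) NA_real_ else
      2 * stats::pnorm(-abs(w$effect / w$se))
    flagged[j] <- flagged[j] || w$flagged
    for (k in seq_len(4)) {
      ec <- env_cols[[specs$coding[k]]][ok, , drop = FALSE]
      inter <- ec * gd
      colnames(inter) <- paste0("gxe_", colnames(ec))
      full <- cbind(b, ec, dosage = gd, inter)
      null <- if (specs$test[k] == "interaction_only") {
        cbind(b, ec, dosage = gd)
      } else {
        cbind(b, ec)
      }
      res <- tryCatch(lrt_nested(full, null, y),
                      error = function(e) list(p = NA_real_,
                                               statistic = NA_real_,
                                               flagged = TRUE))
      p_mat[j, specs$model_id[k]] <- res$p
      lrt_mat[j, specs$model_id[k]] <- res$statistic
      flagged[j] <- flagged[j] || isTRUE(res$flagged)
    }
  }
  out <- data.frame(snp_id = gm$snp_meta$id, chrom = gm$snp_meta$chrom,
                    pos = gm$snp_meta$pos, stringsAsFactors = FALSE)
  for (k in 1:4) out[[paste0("p_model", k)]] <- p_mat[, k]
  for (k in 1:4) out[[paste0("lrt", k)]] <- lrt_mat[, k]
  out$main_effect_p <- main_p
  out$significant_any <- apply(p_mat, 1, function(p) {
    any(!is.na(p) & p < threshold)
  })
  out$flagged <- flagged
  out
}
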