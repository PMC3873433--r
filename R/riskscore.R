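# Aggregate genotype risk scores: top-N SNPs per trait by ascending
# association p with a greedy >=100 kb distance rule, +1/0/-1 per-SNP
# allele-count scoring with the protective-trait (HDL, adiponectin) sign
# reversal, and logistic evaluation of the score against MI.

# Trait-level sign convention: +1 risk-increasing direction except the
# protective biomarkers, whose signs are reversed.
TRAIT_SIGN <- c(ldl = 1, tc = 1, apob = 1, tg = 1, mi = 1, crp = 1,
                hdl = -1, adiponectin = -1)

#' Select score alleles from association results
#'
#' Greedy sweep in ascending p order: a candidate SNP is kept iff its
#' distance to every already-kept SNP on the same chromosome is at least
#' `min_distance` (inclusive). Stops at `n_top` kept SNPs or exhaustion.
#' The scored allele is the allele associated with a higher trait level
#' (the counted allele when `effect > 0`, the other allele otherwise), and
#' each entry carries the trait-level sign: +1 for LDL, total cholesterol,
#' apoB, triglycerides, CRP and MI; -1 for HDL and adiponectin.
#'
#' @param assoc_results Association data frame with `snp_id`, `chrom`,
#'   `pos`, `effect` (or `z`), `p`, `reference_allele`, and a `trait`
#'   column or the `trait` argument.
#' @param n_top Maximum number of SNPs (N) in the score.
#' @param min_distance Minimum pairwise distance in bp (default 100 kb).
#' @param trait Trait label (used for the sign); defaults to the results'
#'   `trait` column.
#' @param sign_map Named trait-to-sign vector; defaults to the standard
#'   convention above.
#' @return A `score_allele_set`: data frame `snp_id`, `chrom`, `pos`,
#'   `scored_allele` (`"counted"`/`"other"`), `sign`, `trait`, `p`,
#'   sorted by ascending source p.
#' @export
select_score_alleles <- function(assoc_results, n_top,
                                 min_distance = 100000, trait = NULL,
                                 sign_map = TRAIT_SIGN) {
  if (n_top <= 0) stop("n_top must be positive")
  res <- assoc_results[!is.na(assoc_results$p), , drop = FALSE]
  if (is.null(trait)) {
    trait <- if ("trait" %in% names(res)) res$trait else "mi"
  }
  res$trait <- rep_len(trait, nrow(res))
  res <- res[order(res$p), , drop = FALSE]
  dir <- if ("effect" %in% names(res) && !all(is.na(res$effect)))
    res$effect else res$z
  kept <- integer(0)
  for (i in seq_len(nrow(res))) {
    if (length(kept) >= n_top) break
    same_chr <- kept[res$chrom[kept] == res$chrom[i]]
    if (length(same_chr) == 0 ||
        all(abs(res$pos[same_chr] - res$pos[i]) >= min_distance)) {
      kept <- c(kept, i)
    }
  }
  sign <- unname(sign_map[res$trait[kept]])
  sign[is.na(sign)] <- 1
  out <- data.frame(snp_id = res$snp_id[kept], chrom = res$chrom[kept],
                    pos = res$pos[kept],
                    scored_allele = ifelse(dir[kept] >= 0, "counted",
                                           "other"),
                    sign = sign, trait = res$trait[kept], p = res$p[kept],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("score_allele_set", "data.frame")
  out
}

#' Score subjects against a score-allele set
#'
#' Per entry: +1 when the subject is homozygous for the scored (trait-
#' raising) allele, -1 when homozygous for the other allele, 0 when
#' heterozygous or missing; the contribution is multiplied by the entry's
#' trait-level sign and summed. Integer scores bounded by the entry count.
#'
#' @param gm A [genotype_matrix()] covering the set's SNPs.
#' @param set A `score_allele_set` from [select_score_alleles()].
#' @return Named integer vector of per-subject scores.
#' @export
score_subjects <- function(gm, set) {
  stopifnot(inherits(gm, "genotype_matrix"))
  idx <- match(set$snp_id, gm$snp_meta$id)
  if (anyNA(idx)) stop("score set references SNPs absent from genotypes")
  g <- gm$calls[, idx, drop = FALSE]
  # homozygous counted allele = 2, homozygous other = 0
  contrib <- matrix(0L, nrow(g), ncol(g))
  contrib[g == 2L] <- 1L
  contrib[g == 0L] <- -1L
  flip <- set$scored_allele == "other"
  contrib[, flip] <- -contrib[, flip]
  contrib <- sweep(contrib, 2, set$sign, `*`)
  scores <- as.integer(rowSums(contrib))
  names(scores) <- rownames(gm$calls)
  scores
}

#' Evaluate a risk score against MI status
#'
#' Logistic regression of case status on the integer score (plus optional
#' covariates); reports the per-unit log-odds, its SE, Wald z and p.
#'
#' @param scores Numeric per-subject scores.
#' @param status 0/1 case status.
#' @param covariates Optional adjustment covariates.
#' @return List: `effect`, `se`, `z`, `p`, `n`.
#' @export
evaluate_score <- function(scores, status, covariates = NULL) {
  stopifnot(length(scores) == length(status))
  if (!all(status %in% c(0, 1))) stop("status must be 0/1")
  if (length(unique(status)) < 2) stop("status has a single class")
  if (stats::var(scores) == 0) stop("score is constant")
  cv <- prep_covariates(covariates)
  check_full_rank(cv)
  design <- cbind(1, if (is.null(cv)) NULL else cv, score = scores)
  w <- logistic_wald(design, status)
  z <- w$effect / w$se
  list(effect = w$effect, se = w$se, z = z, p = 2 * stats::pnorm(-abs(z)),
       n = length(status))
}

#' Merge score-allele candidate lists across traits
#'
#' Concatenates per-trait association results, deduplicates SNPs keeping
#' the entry with the smaller source p, and re-applies the distance rule
#' across the merged list via [select_score_alleles()].
#'
#' @param assoc_list Named list of association data frames (names = trait).
#' @param n_top,min_distance,sign_map See [select_score_alleles()].
#' @return A `score_allele_set`.
#' @export
merge_score_candidates <- function(assoc_list, n_top, min_distance = 100000,
                                   sign_map = TRAIT_SIGN) {
  pooled <- do.call(rbind, lapply(names(assoc_list), function(tr) {
    r <- assoc_list[[tr]]
    r$trait <- tr
    r[, c("snp_id", "chrom", "pos", "reference_allele", "effect", "z", "p",
          "trait")]
  }))
  pooled <- pooled[!is.na(pooled$p), ]
  pooled <- pooled[order(pooled$p), ]
  pooled <- pooled[!duplicated(pooled$snp_id), ]
  select_score_alleles(pooled, n_top, min_distance, trait = pooled$trait,
                       sign_map = sign_map)
}

#' Sweep score sizes and trait combinations
#'
#' For each N in `n_grid` and each element of `trait_sets` (a name or a
#' vector of names into `assoc_by_trait`), derives a score-allele set,
#' scores the evaluation subjects, and tests the score against MI.
#'
#' @param assoc_by_trait Named list of association data frames (derivation
#'   cohort results per trait; may include `"mi"`).
#' @param n_grid Integer vector of score sizes N.
#' @param trait_sets List of trait-name vectors to combine; default every
#'   single trait plus the all-traits merge.
#' @param gm Evaluation-cohort [genotype_matrix()].
#' @param status Evaluation-cohort 0/1 MI status.
#' @param min_distance Distance rule in bp.
#' @param covariates Optional evaluation covariates.
#' @return Data frame: `trait_set`, `n_requested`, `n_snps`, `effect`,
#'   `se`, `z`, `p`.
#' @export
sweep_thresholds <- function(assoc_by_trait, n_grid, gm, status,
                             trait_sets = NULL, min_distance = 100000,
                             covariates = NULL) {
  if (is.null(trait_sets)) {
    trait_sets <- as.list(names(assoc_by_trait))
    if (length(assoc_by_trait) > 1) {
      trait_sets <- c(trait_sets, list(names(assoc_by_trait)))
    }
  }
  rows <- list()
  for (ts in trait_sets) {
    label <- paste(ts, collapse = "+")
    for (n_top in n_grid) {
      set <- if (length(ts) == 1) {
        select_score_alleles(assoc_by_trait[[ts]], n_top, min_distance,
                             trait = ts)
      } else {
        merge_score_candidates(assoc_by_trait[ts], n_top, min_distance)
      }
      sc <- score_subjects(gm, set)
      ev <- tryCatch(evaluate_score(sc, status, covariates),
                     error = function(e) list(effect = NA, se = NA, z = NA,
                                              p = NA))
      rows[[length(rows) + 1]] <- data.frame(
        trait_set = label, n_requested = n_top, n_snps = nrow(set),
        effect = ev$effect, se = ev$se, z = ev$z, p = ev$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
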