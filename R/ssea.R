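# SNP-set enrichment analysis: gene sets become eSNP sets through the
# gene-to-eSNP map, and each set's association p-values are tested as a
# group with a one-sided Kolmogorov-Smirnov test against the background of
# all other mapped eSNPs (or against Uniform(0,1)).

#' Map a gene set to its eSNPs
#'
#' Takes the union of eSNPs over the set's genes (no double counting),
#' intersects with the available association results, and optionally thins
#' by distance, keeping the smallest-p SNP per `ld_thin_distance` window to
#' damp LD-driven dependence.
#'
#' @param genes Character vector of gene ids (one gene set).
#' @param esnp_map Data frame `gene_id`, `snp_id` (see [read_esnp_map()]).
#' @param assoc_results Association data frame keyed by `snp_id` with `p`
#'   (and `chrom`, `pos` when thinning).
#' @param ld_thin_distance Window in bp; `NULL` disables thinning.
#' @return Character vector of SNP ids (possibly empty).
#' @export
map_set_to_snps <- function(genes, esnp_map, assoc_results,
                            ld_thin_distance = NULL) {
  snps <- unique(esnp_map$snp_id[esnp_map$gene_id %in% genes])
  snps <- intersect(snps, assoc_results$snp_id)
  if (length(snps) == 0 || is.null(ld_thin_distance)) return(snps)
  sub <- assoc_results[match(snps, assoc_results$snp_id),
                       c("snp_id", "chrom", "pos", "p")]
  sub <- sub[order(sub$p), ]
  kept <- integer(0)
  for (i in seq_len(nrow(sub))) {
    close_by <- kept[sub$chrom[kept] == sub$chrom[i] &
                       abs(sub$pos[kept] - sub$pos[i]) < ld_thin_distance]
    if (length(close_by) == 0) kept <- c(kept, i)
  }
  sub$snp_id[sort(kept)]
}

# One-sided (toward stochastically smaller x) two-sample KS D+ of x against
# a background y: sup over x's jumps of F_x - F_y.
ks_dplus_two_sample <- function(x, y) {
  x <- sort(x)
  fy <- stats::ecdf(y)
  max(seq_along(x) / length(x) - fy(x))
}

# One-sided one-sample D+ against Uniform(0,1).
ks_dplus_uniform <- function(x) {
  x <- sort(x)
  max(seq_along(x) / length(x) - x)
}

#' Kolmogorov-Smirnov enrichment test of a p-value set
#'
#' Tests whether the set's association p-values are stochastically smaller
#' than a background (one-sided, enrichment toward small p). In two-sample
#' mode the background is the supplied vector (typically all mapped eSNPs
#' outside the set); in one-sample mode the reference is Uniform(0,1).
#' The asymptotic p-value is replaced by a seeded permutation p-value
#' (equal-size resamples from the set-plus-background universe) when the
#' set is smaller than `perm_below`.
#'
#' @param set_pvalues P-values of the set's SNPs, in (0, 1].
#' @param background_pvalues Background p-values, or `NULL` for one-sample
#'   mode.
#' @param perm_below Set size below which a permutation p is used
#'   (two-sample mode only).
#' @param n_perm Number of permutation draws.
#' @param seed Seed for the permutation draws.
#' @return List: `n_snps`, `ks_statistic` (D+, in \[0, 1\]), `ks_p`,
#'   `method` (`"two_sample"`/`"one_sample"`), `p_source`
#'   (`"asymptotic"`/`"permutation"`).
#' @export
ks_enrichment <- function(set_pvalues, background_pvalues = NULL,
                          perm_below = 30, n_perm = 10000, seed = 1) {
  x <- set_pvalues
  if (length(x) == 0) stop("empty p-value set")
  if (any(is.na(x)) || any(x <= 0) || any(x > 1)) {
    stop("set p-values must lie in (0, 1]")
  }
  if (is.null(background_pvalues)) {
    d <- ks_dplus_uniform(x)
    p <- suppressWarnings(
      stats::ks.test(x, "punif", alternative = "greater")$p.value)
    return(list(n_snps = length(x), ks_statistic = d, ks_p = p,
                method = "one_sample", p_source = "asymptotic"))
  }
  y <- background_pvalues
  if (length(y) < length(x)) stop("background smaller than set")
  d <- ks_dplus_two_sample(x, y)
  if (length(x) >= perm_below) {
    p <- suppressWarnings(
      stats::ks.test(x, y, alternative = "greater")$p.value)
    src <- "asymptotic"
  } else {
    p <- ks_permutation_p(x, y, d, n_perm, seed)
    src <- "permutation"
  }
  list(n_snps = length(x), ks_statistic = d, ks_p = p,
       method = "two_sample", p_source = src)
}

# Permutation p: draw size-s subsets from the pooled universe and compare
# each against its complement. With R_i the rank of the i-th smallest drawn
# value in the sorted universe, the complement ECDF at that value is
# (R_i - i) / m, so D+ = max_i(i/s - (R_i - i)/m) — fully vectorized over
# draws.
ks_permutation_p <- function(x, y, d_obs, n_perm, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  univ <- sort(c(x, y))
  n <- length(univ)
  s <- length(x)
  m <- n - s
  ranks <- matrix(0L, n_perm, s)
  for (b in seq_len(n_perm)) ranks[b, ] <- sort(sample.int(n, s))
  i_over_s <- matrix(seq_len(s) / s, n_perm, s, byrow = TRUE)
  i_mat <- matrix(seq_len(s), n_perm, s, byrow = TRUE)
  dplus <- apply(i_over_s - (ranks - i_mat) / m, 1, max)
  (1 + sum(dplus >= d_obs - 1e-12)) / (n_perm + 1)
}

#' Run SNP-set enrichment over a gene-set collection
#'
#' Maps every set to eSNPs, skips sets mapping to fewer than `min_set_size`
#' SNPs (logged in the `skipped` attribute), tests each eligible set against
#' the shared background universe, and reports Benjamini-Hochberg q-values
#' alongside raw KS p-values. QQ data (observed sorted -log10 p against
#' uniform expected quantiles) is returned per set for plotting.
#'
#' @param collection Named list of gene-id vectors ([read_gmt()] output or
#'   the generator's `sets`).
#' @param esnp_map Data frame `gene_id`, `snp_id`.
#' @param assoc_results Association data frame with `snp_id`, `p` (and
#'   `chrom`, `pos` if thinning).
#' @param mode `"two_sample"` (background = mapped eSNPs outside the set) or
#'   `"one_sample"` (Uniform reference).
#' @param min_set_size Minimum mapped SNPs per set.
#' @param ld_thin_distance Optional thinning window passed to
#'   [map_set_to_snps()].
#' @param perm_below,n_perm,seed Permutation controls, see [ks_enrichment()].
#' @return Data frame sorted ascending by `ks_p`: `set`, `n_genes`,
#'   `n_snps`, `ks_statistic`, `ks_p`, `q`, `method`, `p_source`; attributes
#'   `skipped` (named reasons) and `qq` (named list of two-column data
#'   frames `expected`, `observed` in -log10 units).
#' @export
run_ssea <- function(collection, esnp_map, assoc_results,
                     mode = c("two_sample", "one_sample"),
                     min_set_size = 5, ld_thin_distance = NULL,
                     perm_below = 30, n_perm = 10000, seed = 1) {
  mode <- match.arg(mode)
  if (length(collection) == 0) stop("empty gene-set collection")
  assoc_results <- assoc_results[!is.na(assoc_results$p), , drop = FALSE]
  set_snps <- lapply(collection, map_set_to_snps, esnp_map = esnp_map,
                     assoc_results = assoc_results,
                     ld_thin_distance = ld_thin_distance)
  universe <- unique(esnp_map$snp_id)
  universe <- intersect(universe, assoc_results$snp_id)
  p_of <- stats::setNames(assoc_results$p,
                          assoc_results$snp_id)[universe]
  eligible <- lengths(set_snps) >= min_set_size
  skipped <- stats::setNames(
    sprintf("mapped to %d SNPs (< %d)", lengths(set_snps)[!eligible],
            min_set_size),
    names(collection)[!eligible])
  rows <- vector("list", sum(eligible))
  qq <- vector("list", sum(eligible))
  k <- 0
  for (nm in sort(names(collection)[eligible])) {
    k <- k + 1
    snps <- set_snps[[nm]]
    px <- unname(p_of[snps])
    bg <- if (mode == "two_sample") unname(p_of[setdiff(universe, snps)])
          else NULL
    res <- ks_enrichment(px, bg, perm_below = perm_below, n_perm = n_perm,
                         seed = seed + k)
    rows[[k]] <- data.frame(set = nm, n_genes = length(collection[[nm]]),
                            n_snps = res$n_snps,
                            ks_statistic = res$ks_statistic,
                            ks_p = res$ks_p, method = res$method,
                            p_source = res$p_source,
                            stringsAsFactors = FALSE)
    srt <- sort(px)
    qq[[k]] <- data.frame(expected = -log10(stats::ppoints(length(srt))),
                          observed = sort(-log10(srt), decreasing = TRUE))
    names(qq)[k] <- nm
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$ks_p, method = "BH")
  out <- out[order(out$ks_p), c("set", "n_genes", "n_snps", "ks_statistic",
                                "ks_p", "q", "method", "p_source")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "qq") <- qq
  out
}

#' Write per-set QQ data to TSV files
#'
#' @param ssea_result Output of [run_ssea()].
#' @param dir Output directory; one `<set>.qq.tsv` per set.
#' @param sets Optional character vector restricting which sets to write.
#' @return Invisibly, the directory.
#' @export
write_qq_data <- function(ssea_result, dir, sets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qq <- attr(ssea_result, "qq")
  if (!is.null(sets)) qq <- qq[intersect(sets, names(qq))]
  for (nm in names(qq)) {
    utils::write.table(qq[[nm]], file.path(dir, paste0(nm, ".qq.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
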