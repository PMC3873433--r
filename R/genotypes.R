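#' Construct a genotype matrix object
#'
#' The central container of the pipeline: hard-call genotypes coded as the
#' number of copies of the non-reference (counted) allele per sample, with
#' per-SNP metadata. Missing calls are `NA`.
#'
#' @param calls Integer matrix, samples in rows and SNPs in columns, values in
#'   \{0, 1, 2, NA\}. Row names (if any) are taken as sample ids when
#'   `sample_ids` is not given.
#' @param snp_meta Data frame with one row per SNP and columns `id`, `chrom`,
#'   `pos` (1-based), `ref`, `alt`.
#' @param sample_ids Character vector of unique sample identifiers.
#' @return An object of class `genotype_matrix`: a list with elements `calls`
#'   (integer matrix with dimnames set), and `snp_meta`.
#' @export
genotype_matrix <- function(calls, snp_meta, sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(calls)))
  }
  stopifnot(
    nrow(snp_meta) == ncol(calls),
    length(sample_ids) == nrow(calls),
    all(c("id", "chrom", "pos", "ref", "alt") %in% names(snp_meta))
  )
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyDuplicated(snp_meta$id)) stop("SNP ids must be unique")
  if (any(snp_meta$pos <= 0)) stop("positions must be strictly positive")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("genotype calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(sample_ids, snp_meta$id)
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  rownames(snp_meta) <- NULL
  structure(list(calls = calls, snp_meta = snp_meta),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param gm A `genotype_matrix`.
#' @param samples,snps Index, logical or character selectors; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
subset_genotypes <- function(gm, samples = NULL, snps = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  meta <- gm$snp_meta
  if (!is.null(samples)) calls <- calls[samples, , drop = FALSE]
  if (!is.null(snps)) {
    if (is.character(snps)) snps <- match(snps, meta$id)
    calls <- calls[, snps, drop = FALSE]
    meta <- meta[snps, , drop = FALSE]
  }
  genotype_matrix(calls, meta, rownames(calls))
}

#' Per-SNP allele frequency of the counted (alt) allele
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric vector of alt-allele frequencies, `NaN` where all calls are
#'   missing.
#' @export
alt_freq <- function(gm) {
  colMeans(gm$calls, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#'
#' @param gm A `genotype_matrix`.
#' @return Numeric vector, `pmin(p, 1 - p)` of the alt-allele frequency.
#' @export
maf <- function(gm) {
  p <- alt_freq(gm)
  pmin(p, 1 - p)
}
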