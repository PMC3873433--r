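# File formats: genotype TSV and GT-only VCF 4.2, GMT gene sets, eSNP map,
# phenotype tables, truth JSON. Positions are 1-based throughout; the missing
# token in TSVs is NA.

#' Read a genotype matrix from TSV or VCF
#'
#' TSV dialect: header row of SNP ids, first column `sample_id`, cells in
#' \{0, 1, 2, NA\}. SNP metadata for TSV input is reconstructed from a
#' companion metadata file when `meta_path` is given, otherwise ids become
#' `snp` columns with placeholder chrom/pos (1-based running positions).
#' VCF input: GT fields parsed as the count of ALT alleles; `./.` and `.|.`
#' are missing; multi-allelic records are skipped with a logged count
#' (attribute `n_skipped_multiallelic`).
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param meta_path Optional SNP metadata TSV (`id`, `chrom`, `pos`, `ref`,
#'   `alt`) for TSV genotype input.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "vcf") return(read_vcf_gt(path))
  dat <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           colClasses = NA)
  if (names(dat)[1] != "sample_id") {
    stop("malformed header: first column must be 'sample_id' (line 1)")
  }
  calls <- as.matrix(dat[, -1, drop = FALSE])
  bad <- which(!(calls %in% c(0, 1, 2) | is.na(calls)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-biallelic genotype value at line %d",
                 bad[1, "row"] + 1L))
  }
  if (!is.null(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    meta <- data.frame(id = colnames(calls), chrom = "chr1",
                       pos = seq_len(ncol(calls)), ref = "A", alt = "B",
                       stringsAsFactors = FALSE)
  }
  genotype_matrix(calls, meta, as.character(dat$sample_id))
}

#' Write a genotype matrix as TSV (plus SNP metadata TSV)
#'
#' @param gm A [genotype_matrix()].
#' @param path Output TSV path; metadata goes to `paste0(path, ".meta")`
#'   unless `meta_path` overrides it.
#' @param meta_path Optional metadata output path.
#' @return Invisibly, `path`.
#' @export
write_genotypes_tsv <- function(gm, path, meta_path = paste0(path, ".meta")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  out <- data.frame(sample_id = rownames(gm$calls), gm$calls,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$snp_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Minimal GT-only VCF 4.2 reader. Field layout is fixed by the standard, so a
# split on tabs suffices; anything beyond GT in FORMAT is ignored.
read_vcf_gt <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (length(body) == 0 || !startsWith(body[1], "#CHROM")) {
    stop("malformed VCF: missing #CHROM header line")
  }
  header <- strsplit(sub("^#", "", body[1]), "\t", fixed = TRUE)[[1]]
  if (length(header) < 10) stop("VCF has no sample columns")
  sample_ids <- header[-(1:9)]
  records <- body[-1]
  n_skip <- 0L
  rows <- vector("list", length(records))
  meta <- vector("list", length(records))
  for (i in seq_along(records)) {
    f <- strsplit(records[i], "\t", fixed = TRUE)[[1]]
    if (grepl(",", f[5], fixed = TRUE)) {  # multi-allelic ALT
      n_skip <- n_skip + 1L
      next
    }
    gt_idx <- match("GT", strsplit(f[9], ":", fixed = TRUE)[[1]])
    if (is.na(gt_idx)) stop("VCF record without GT at line: ", f[3])
    gt <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gt_idx)
    alleles <- strsplit(gt, "[/|]")
    dosage <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
    rows[[i]] <- dosage
    meta[[i]] <- data.frame(id = f[3], chrom = f[1], pos = as.integer(f[2]),
                            ref = f[4], alt = f[5], stringsAsFactors = FALSE)
  }
  keep <- !vapply(rows, is.null, logical(1))
  calls <- do.call(cbind, rows[keep])
  snp_meta <- do.call(rbind, meta[keep])
  gm <- genotype_matrix(calls, snp_meta, sample_ids)
  attr(gm, "n_skipped_multiallelic") <- n_skip
  gm
}

#' Write a genotype matrix as a GT-only VCF 4.2 file
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path (uncompressed text).
#' @return Invisibly, `path`.
#' @export
write_vcf_gt <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm$calls)), collapse = "\t")),
             con)
  m <- gm$snp_meta
  for (j in seq_len(ncol(gm$calls))) {
    g <- gm$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(m$chrom[j], m$pos[j], m$id[j], m$ref[j], m$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then tab-separated gene ids.
#' Duplicate genes within a set are collapsed with a warning; duplicate set
#' names are an error.
#'
#' @param path GMT file.
#' @return A `gene_set_collection`: named list of character gene-id vectors,
#'   with a `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names <- vapply(parts, `[`, "", 1)
  if (anyDuplicated(names)) {
    stop("duplicate gene set name: ", names[duplicated(names)][1])
  }
  sets <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes collapsed in set ", p[1])
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- names
  if (any(lengths(sets) == 0)) stop("empty gene set: ",
                                    names[lengths(sets) == 0][1])
  desc <- vapply(parts, `[`, "", 2)
  names(desc) <- names
  structure(sets, description = desc, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of gene-id vectors (or `gene_set_collection`).
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to the
#'   collection's `description` attribute or `"na"`.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
  }
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-to-eSNP map
#'
#' TSV with columns `gene_id`, `snp_id` and optionally `tissue_label`.
#' Duplicate (gene, snp) pairs are collapsed; the number dropped is stored in
#' attribute `n_duplicates_collapsed`.
#'
#' @param path TSV file.
#' @return Data frame with columns `gene_id`, `snp_id`, `tissue_label`.
#' @export
read_esnp_map <- function(path) {
  dat <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("gene_id", "snp_id")) {
    if (!col %in% names(dat)) stop("eSNP map is missing column '", col, "'")
  }
  if (!"tissue_label" %in% names(dat)) dat$tissue_label <- NA_character_
  dup <- duplicated(dat[, c("gene_id", "snp_id")])
  out <- dat[!dup, c("gene_id", "snp_id", "tissue_label")]
  rownames(out) <- NULL
  attr(out, "n_duplicates_collapsed") <- sum(dup)
  out
}

#' Read a phenotype/covariate table
#'
#' Requires `sample_id` and `status` columns; all other columns (biomarkers,
#' environment, covariates) are optional and passed through.
#'
#' @param path TSV file.
#' @return Data frame keyed by `sample_id`.
#' @export
read_phenotypes <- function(path) {
  dat <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "status")) {
    if (!col %in% names(dat)) {
      stop("phenotype table is missing required column '", col, "'")
    }
  }
  if (!all(dat$status %in% c(0, 1))) stop("status must be 0/1")
  dat
}

#' Write a cohort's phenotype table as TSV
#'
#' @param phenotypes Data frame with `sample_id` and `status`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
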