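# Synthetic two-cohort nested case-control study generator. Emulates the
# statistical structure the downstream stages assume: Hardy-Weinberg
# genotypes in LD blocks, an additive logistic disease model with the
# intercept tuned to the case:control design ratio, standardized quantitative
# biomarkers, gene-set/eSNP structure with enriched sets, and SNP-by-
# environment interaction effects with zero marginal SNP effect.

#' Simulation configuration for the synthetic two-cohort study
#'
#' Defaults describe the emulated design: two sex-stratified cohorts of
#' 464 + 945 and 425 + 878 subjects (1:2 case:control), common-variant
#' genotypes in 10-SNP LD blocks at 25 kb spacing, modest additive effects
#' on disease and biomarkers, 100 gene sets of which a small fraction carry
#' true eSNP signal, and a pair of pure-interaction SNPs.
#'
#' @param n_cases_per_cohort,n_controls_per_cohort Integer vectors (recycled
#'   to 2 cohorts) of case/control counts.
#' @param n_snps Number of SNPs.
#' @param maf_range Interval in (0, 0.5] from which block MAFs are drawn.
#' @param n_causal_binary Number of SNPs with a disease main effect.
#' @param or_causal Per-allele odds ratio of disease-causal SNPs.
#' @param n_causal_quant Causal SNPs per quantitative trait.
#' @param beta_quant Per-allele effect on a quantitative trait, in residual
#'   SD units (effect signs are drawn at random per SNP).
#' @param ld_block_size SNPs per LD block.
#' @param ld_r Target pairwise genotype correlation within a block, in
#'   \[0, 1). The latent copula correlation is calibrated so the realized
#'   genotype correlation matches this value.
#' @param n_gene_sets,genes_per_set,esnps_per_gene Gene-set structure.
#' @param enriched_set_fraction Fraction of sets given true eSNP signal.
#' @param causal_esnp_fraction Fraction of an enriched set's eSNPs drawn from
#'   causal SNPs.
#' @param gxe_snp_count Number of pure-interaction SNPs (no marginal effect).
#' @param gxe_beta Interaction log-odds per allele per environment SD.
#' @param missing_rate Per-call missingness probability.
#' @param pool_factor Oversampling factor for the subject pool from which the
#'   exact case/control counts are drawn (nested case-control sampling).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_cases_per_cohort = c(464L, 425L),
                       n_controls_per_cohort = c(945L, 878L),
                       n_snps = 2000L,
                       maf_range = c(0.05, 0.5),
                       n_causal_binary = 20L,
                       or_causal = 1.4,
                       n_causal_quant = 20L,
                       beta_quant = 0.25,
                       ld_block_size = 10L,
                       ld_r = 0.5,
                       n_gene_sets = 100L,
                       genes_per_set = 4L,
                       esnps_per_gene = 5L,
                       enriched_set_fraction = 0.03,
                       causal_esnp_fraction = 0.5,
                       gxe_snp_count = 2L,
                       gxe_beta = 0.5,
                       missing_rate = 0.005,
                       pool_factor = 1.5,
                       seed = 1L) {
  cfg <- list(n_cases_per_cohort = rep_len(as.integer(n_cases_per_cohort), 2),
              n_controls_per_cohort =
                rep_len(as.integer(n_controls_per_cohort), 2),
              n_snps = as.integer(n_snps), maf_range = maf_range,
              n_causal_binary = as.integer(n_causal_binary),
              or_causal = or_causal,
              n_causal_quant = as.integer(n_causal_quant),
              beta_quant = beta_quant,
              ld_block_size = as.integer(ld_block_size), ld_r = ld_r,
              n_gene_sets = as.integer(n_gene_sets),
              genes_per_set = as.integer(genes_per_set),
              esnps_per_gene = as.integer(esnps_per_gene),
              enriched_set_fraction = enriched_set_fraction,
              causal_esnp_fraction = causal_esnp_fraction,
              gxe_snp_count = as.integer(gxe_snp_count),
              gxe_beta = gxe_beta, missing_rate = missing_rate,
              pool_factor = pool_factor, seed = as.integer(seed))
  counts <- c(cfg$n_cases_per_cohort, cfg$n_controls_per_cohort, cfg$n_snps,
              cfg$n_causal_binary, cfg$n_causal_quant, cfg$ld_block_size,
              cfg$n_gene_sets, cfg$genes_per_set, cfg$esnps_per_gene,
              cfg$gxe_snp_count)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$n_causal_binary > cfg$n_snps || cfg$n_causal_quant > cfg$n_snps) {
    stop("n_causal_* must not exceed n_snps")
  }
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (cfg$ld_r < 0 || cfg$ld_r >= 1) stop("ld_r must be in [0, 1)")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (cfg$or_causal <= 0) stop("or_causal must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# P(Z1 < q, Z2 < q) for a standard bivariate normal with correlation rho,
# by one-dimensional quadrature over the conditional CDF.
binorm_joint_lower <- function(q, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(q)^2)
  s <- sqrt(1 - rho^2)
  stats::integrate(function(z) {
    stats::pnorm((q - rho * z) / s) * stats::dnorm(z)
  }, -Inf, q, rel.tol = 1e-10)$value
}

# Latent correlation such that thresholded Bernoulli alleles at frequency p
# have (phi) correlation r. Genotypes (sums of two independent allele copies)
# inherit the same correlation.
calibrate_latent_rho <- function(p, r) {
  if (r <= 0) return(0)
  q <- stats::qnorm(p)
  phi_of <- function(rho) {
    (binorm_joint_lower(q, rho) - p^2) / (p * (1 - p)) - r
  }
  stats::uniroot(phi_of, c(1e-6, 1 - 1e-6), tol = 1e-8)$root
}

#' Simulate hard-call genotypes in LD blocks
#'
#' Each SNP is drawn at Hardy-Weinberg proportions for its MAF. SNPs are
#' grouped into blocks of `ld_block_size` sharing one MAF; within a block the
#' two allele copies are thresholded equicorrelated Gaussians whose latent
#' correlation is calibrated so the realized pairwise genotype correlation is
#' approximately `ld_r`. Positions run at fixed 25 kb spacing on synthetic
#' chromosomes (blocks never straddle a chromosome), so a 10-SNP block spans
#' more than 100 kb and distance-based pruning is exercised. Missing calls
#' are injected completely at random at `missing_rate`.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of samples to draw.
#' @param seed Optional integer seed (defaults to `config$seed`).
#' @return A [genotype_matrix()] with attribute `block_id` (integer per SNP).
#' @export
simulate_genotypes <- function(config, n_samples, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), n_samples > 0)
  if (!is.null(seed)) set.seed(seed)
  n_snps <- config$n_snps
  bs <- max(1L, min(config$ld_block_size, n_snps))
  n_blocks <- ceiling(n_snps / bs)
  block_id <- rep(seq_len(n_blocks), each = bs)[seq_len(n_snps)]
  block_maf <- stats::runif(n_blocks, config$maf_range[1], config$maf_range[2])

  calls <- matrix(0L, n_samples, n_snps)
  # latent rho is a function of (maf, ld_r) only; solve once per block
  for (b in seq_len(n_blocks)) {
    idx <- which(block_id == b)
    p <- block_maf[b]
    q <- stats::qnorm(p)
    rho <- if (length(idx) > 1) calibrate_latent_rho(p, config$ld_r) else 0
    g <- matrix(0L, n_samples, length(idx))
    for (copy in 1:2) {
      w <- stats::rnorm(n_samples)
      e <- matrix(stats::rnorm(n_samples * length(idx)), n_samples)
      z <- sqrt(rho) * w + sqrt(1 - rho) * e
      g <- g + (z < q)
    }
    calls[, idx] <- g
  }
  if (config$missing_rate > 0) {
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
  }

  blocks_per_chrom <- max(1L, 250L %/% bs)   # ~250 SNPs per chromosome
  chrom_of_block <- (seq_len(n_blocks) - 1L) %/% blocks_per_chrom + 1L
  chrom <- paste0("chr", chrom_of_block[block_id])
  pos <- integer(n_snps)
  for (cid in unique(chrom_of_block)) {
    idx <- which(chrom_of_block[block_id] == cid)
    pos[idx] <- 25000L * seq_along(idx)
  }
  meta <- data.frame(id = sprintf("snp%05d", seq_len(n_snps)), chrom = chrom,
                     pos = pos, ref = "A", alt = "B",
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, meta)
  attr(gm, "block_id") <- block_id
  attr(gm, "block_maf") <- block_maf[block_id]
  gm
}

# Bisection on the logistic intercept so that mean P(case) hits `target`.
tune_intercept <- function(eta, target) {
  if (target <= 0 || target >= 1) stop("unattainable case fraction")
  f <- function(a) mean(stats::plogis(a + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop("unattainable case fraction")
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

# Draw 0/1 labels from logit(P) = alpha + eta with alpha tuned to
# `target_fraction`, then sample exactly n_cases cases and n_controls
# controls from the pool. Returns selected indices and their labels.
draw_case_control <- function(eta, n_cases, n_controls) {
  n <- n_cases + n_controls
  alpha <- tune_intercept(eta, n_cases / n)
  lab <- stats::rbinom(length(eta), 1L, stats::plogis(alpha + eta))
  cases <- which(lab == 1L)
  controls <- which(lab == 0L)
  if (length(cases) < n_cases || length(controls) < n_controls) {
    stop("subject pool too small for the configured case/control counts")
  }
  sel <- c(sample(cases, n_cases), sample(controls, n_controls))
  sel <- sort(sel)
  list(selected = sel, status = lab[sel], intercept = alpha)
}

# Mean-imputed dosage columns (used only to form simulation linear
# predictors; analysis-side missingness handling is per-SNP complete-case).
dosage_filled <- function(gm, snps) {
  d <- gm$calls[, snps, drop = FALSE]
  for (j in seq_len(ncol(d))) {
    m <- is.na(d[, j])
    if (any(m)) d[m, j] <- round(mean(d[, j], na.rm = TRUE))
  }
  d
}

#' Simulate case/control labels under an additive logistic model
#'
#' Labels follow `logit(P) = intercept + sum(log(or_causal) * dosage) +
#' covariate terms`, with the intercept tuned by bisection so the realized
#' case fraction matches `n_cases / (n_cases + n_controls)`; the exact
#' configured counts are then sampled from the pool.
#'
#' @param gm Pool [genotype_matrix()] (typically oversampled; see
#'   `pool_factor` in [sim_config()]).
#' @param config A [sim_config()].
#' @param cohort Which cohort's counts to use (1 or 2).
#' @param causal_snps Character ids of causal SNPs; default draws
#'   `n_causal_binary` SNPs among those with below-median missingness.
#' @param covariate_logit Optional extra per-subject logit term (covariate
#'   and/or interaction effects).
#' @param seed Optional integer seed.
#' @return List: `selected` (pool row indices), `status` (0/1 for selected),
#'   `causal` (data frame snp_id, log_or), `intercept`.
#' @export
simulate_binary_trait <- function(gm, config, cohort = 1,
                                  causal_snps = NULL,
                                  covariate_logit = NULL, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(causal_snps)) {
    causal_snps <- pick_causal(gm, config$n_causal_binary)
  }
  if (!all(causal_snps %in% gm$snp_meta$id)) {
    stop("causal SNP not present in genotype matrix")
  }
  eta <- rep(0, nrow(gm$calls))
  if (length(causal_snps) > 0 && config$or_causal != 1) {
    d <- dosage_filled(gm, causal_snps)
    eta <- eta + drop(d %*% rep(log(config$or_causal), length(causal_snps)))
  }
  if (!is.null(covariate_logit)) eta <- eta + covariate_logit
  dcc <- draw_case_control(eta, config$n_cases_per_cohort[cohort],
                           config$n_controls_per_cohort[cohort])
  dcc$causal <- data.frame(snp_id = causal_snps,
                           log_or = rep(log(config$or_causal),
                                        length(causal_snps)),
                           stringsAsFactors = FALSE)
  dcc
}

# Causal SNPs are drawn from SNPs that are not missing-heavy, at most one
# per LD block so signals do not stack within a block; min_maf restricts to
# common variants (used for interaction SNPs, whose per-genotype effect is
# only identifiable with enough carriers).
pick_causal <- function(gm, k, exclude = character(0), min_maf = 0) {
  if (k == 0) return(character(0))
  miss <- colMeans(is.na(gm$calls))
  ok <- miss <= stats::median(miss) + 0.01
  if (min_maf > 0) ok <- ok & !is.na(maf(gm)) & maf(gm) >= min_maf
  block <- attr(gm, "block_id")
  if (is.null(block)) block <- seq_len(ncol(gm$calls))
  cand <- which(ok & !(gm$snp_meta$id %in% exclude))
  cand <- cand[!duplicated(block[cand])]
  if (length(cand) < k) stop("not enough eligible SNPs for causal selection")
  gm$snp_meta$id[sample(cand, k)]
}

#' Simulate standardized quantitative biomarkers
#'
#' Seven biomarkers (ldl, hdl, apob, tg, adiponectin, crp, tc), each with its
#' own causal SNP set: `trait = sum(beta * dosage) + N(0, 1)` noise, then
#' standardized to mean 0, SD 1. Effect signs are drawn at random per SNP
#' and recorded in the truth table so sign-sensitive downstream steps (HDL /
#' adiponectin reversal in the risk score) are testable.
#'
#' @param gm A [genotype_matrix()] (the analyzed subjects).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @param architecture Optional data frame (`trait`, `snp_id`, `beta`) fixing
#'   the causal SNPs and effects, e.g. from [draw_quant_architecture()]; used
#'   by [simulate_study()] so both cohorts share one biomarker architecture.
#' @return List: `traits` (data frame, one standardized column per biomarker)
#'   and `truth` (data frame trait, snp_id, beta, scale — beta on the
#'   pre-standardization scale, `scale` the SD divided out).
#' @export
simulate_quantitative_traits <- function(gm, config, seed = NULL,
                                         architecture = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  trait_names <- c("ldl", "hdl", "apob", "tg", "adiponectin", "crp", "tc")
  n <- nrow(gm$calls)
  traits <- as.data.frame(matrix(NA_real_, n, length(trait_names)))
  names(traits) <- trait_names
  truth <- list()
  used <- character(0)
  for (tr in trait_names) {
    if (!is.null(architecture)) {
      arch <- architecture[architecture$trait == tr, , drop = FALSE]
      snps <- arch$snp_id
      beta <- arch$beta
      if (!all(snps %in% gm$snp_meta$id)) {
        stop("architecture references SNPs absent from the genotype matrix")
      }
    } else {
      k <- config$n_causal_quant
      snps <- tryCatch(pick_causal(gm, k, exclude = used),
                       error = function(e) pick_causal(gm, k))
      used <- c(used, snps)
      beta <- config$beta_quant * sample(c(-1, 1), length(snps),
                                         replace = TRUE)
    }
    y <- stats::rnorm(n)
    if (length(snps) > 0 && config$beta_quant != 0) {
      y <- y + drop(dosage_filled(gm, snps) %*% beta)
    }
    s <- stats::sd(y)
    traits[[tr]] <- (y - mean(y)) / s
    truth[[tr]] <- if (length(snps)) {
      data.frame(trait = tr, snp_id = snps, beta = beta, scale = s,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(trait = character(0), snp_id = character(0),
                 beta = numeric(0), scale = numeric(0),
                 stringsAsFactors = FALSE)
    }
  }
  list(traits = traits, truth = do.call(rbind, truth))
}

#' Simulate an environment variable with pure SNP-by-environment interaction
#'
#' Draws a continuous alcohol-like exposure `E ~ N(0, 1)` and regenerates
#' case/control labels from a logit that adds `gxe_beta * dosage * E` for
#' `gxe_snp_count` SNPs that carry no marginal SNP effect — so interaction
#' SNPs show no main effect, as in the motivating design.
#'
#' @param gm Pool [genotype_matrix()].
#' @param config A [sim_config()].
#' @param cohort Cohort index (1 or 2) for the case/control counts.
#' @param main_logit Per-subject logit contribution of the main-effect model
#'   (causal SNPs and covariates); default 0.
#' @param gxe_snps Character ids of interaction SNPs; default draws
#'   `gxe_snp_count` SNPs.
#' @param exclude SNP ids ineligible as interaction SNPs (e.g. main-effect
#'   causal SNPs).
#' @param seed Optional integer seed.
#' @return List: `env` (pool-length numeric), `selected`, `status`,
#'   `gxe_snps`, `intercept`.
#' @export
simulate_environment_with_interaction <- function(gm, config, cohort = 1,
                                                  main_logit = NULL,
                                                  gxe_snps = NULL,
                                                  exclude = character(0),
                                                  seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(gm$calls)
  env <- stats::rnorm(n)
  if (is.null(gxe_snps)) {
    gxe_snps <- pick_causal(gm, config$gxe_snp_count, exclude = exclude,
                            min_maf = 0.2)
  }
  eta <- if (is.null(main_logit)) rep(0, n) else main_logit
  if (length(gxe_snps) > 0 && config$gxe_beta != 0) {
    d <- dosage_filled(gm, gxe_snps)
    eta <- eta + config$gxe_beta * rowSums(d * env)
  }
  dcc <- draw_case_control(eta, config$n_cases_per_cohort[cohort],
                           config$n_controls_per_cohort[cohort])
  list(env = env, selected = dcc$selected, status = dcc$status,
       gxe_snps = gxe_snps, intercept = dcc$intercept)
}

#' Simulate gene sets and the gene-to-eSNP map
#'
#' Synthetic gene labels are grouped into named sets; each gene maps to
#' `esnps_per_gene` SNP ids. Enriched sets (an `enriched_set_fraction` share)
#' draw a `causal_esnp_fraction` of their eSNPs from the supplied causal
#' SNPs; null sets draw from SNPs outside the causal SNPs' LD blocks —
#' without replacement across sets when capacity allows, so null sets are
#' disjoint and their enrichment p-values independent.
#'
#' @param config A [sim_config()].
#' @param snp_ids All available SNP ids (association-result universe).
#' @param causal_snps SNP ids with true signal.
#' @param block_id Optional integer LD-block label per `snp_ids` entry; used
#'   to keep null sets clear of causal blocks.
#' @param seed Optional integer seed.
#' @return List: `sets` (`gene_set_collection` of gene ids), `esnp_map`
#'   (data frame gene_id, snp_id, tissue_label), `enriched_sets` (names).
#' @export
simulate_gene_sets_and_esnp_map <- function(config, snp_ids,
                                            causal_snps = character(0),
                                            block_id = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  if (!all(causal_snps %in% snp_ids)) {
    stop("gene set generation references unknown SNP ids")
  }
  n_sets <- config$n_gene_sets
  gps <- config$genes_per_set
  epg <- config$esnps_per_gene
  n_enriched <- round(config$enriched_set_fraction * n_sets)
  set_names <- sprintf("set%03d", seq_len(n_sets))
  if (n_sets == 0) {
    return(list(sets = structure(list(), class = "gene_set_collection"),
                esnp_map = data.frame(gene_id = character(0),
                                      snp_id = character(0),
                                      tissue_label = character(0)),
                enriched_sets = character(0)))
  }
  enriched <- if (n_enriched > 0) sample(set_names, n_enriched) else character(0)

  snps_per_set <- gps * epg
  null_pool <- setdiff(snp_ids, causal_snps)
  if (!is.null(block_id) && length(causal_snps) > 0) {
    # keep null sets clear of causal LD blocks when enough SNPs remain
    causal_blocks <- unique(block_id[snp_ids %in% causal_snps])
    pool2 <- snp_ids[!(block_id %in% causal_blocks)]
    if (length(pool2) >= snps_per_set) null_pool <- pool2
  }
  if (length(null_pool) < snps_per_set) {
    stop("too few SNPs to build gene sets of the configured size")
  }
  n_null_needed <- (n_sets - n_enriched) * snps_per_set
  global_wor <- n_null_needed <= length(null_pool)
  null_queue <- if (global_wor) sample(null_pool, n_null_needed) else NULL
  qpos <- 0L

  sets <- list()
  map <- vector("list", n_sets)
  gene_counter <- 0L
  for (i in seq_len(n_sets)) {
    nm <- set_names[i]
    genes <- sprintf("gene%05d", gene_counter + seq_len(gps))
    gene_counter <- gene_counter + gps
    if (nm %in% enriched) {
      k_causal <- min(round(config$causal_esnp_fraction * snps_per_set),
                      length(causal_snps))
      from_causal <- if (k_causal > 0) sample(causal_snps, k_causal)
                     else character(0)
      filler <- sample(null_pool, snps_per_set - k_causal)
      snps <- sample(c(from_causal, filler))
    } else if (global_wor) {
      snps <- null_queue[qpos + seq_len(snps_per_set)]
      qpos <- qpos + snps_per_set
    } else {
      snps <- sample(null_pool, min(snps_per_set, length(null_pool)))
    }
    sets[[nm]] <- genes
    map[[i]] <- data.frame(gene_id = rep(genes, each = epg)[seq_along(snps)],
                           snp_id = snps, tissue_label = "synthetic",
                           stringsAsFactors = FALSE)
  }
  collection <- structure(sets,
                          description = stats::setNames(
                            ifelse(set_names %in% enriched,
                                   "enriched", "null"), set_names),
                          class = "gene_set_collection")
  list(sets = collection, esnp_map = do.call(rbind, map),
       enriched_sets = sort(enriched))
}

#' Simulate one full cohort
#'
#' Oversamples a subject pool, draws case/control labels from the additive
#' disease model (plus any interaction term), selects the exact configured
#' counts, and attaches standardized biomarkers, environment, and matching
#' covariates (age and smoking with the mild case-control imbalance typical
#' of nested MI case-control tables; unconditional analysis downstream).
#'
#' @param config A [sim_config()].
#' @param cohort 1 or 2.
#' @param causal_snps,gxe_snps Optional pre-chosen SNP id sets (shared across
#'   cohorts by [simulate_study()]).
#' @param seed Integer seed; default derives from `config$seed` and `cohort`.
#' @return List with `genotypes` ([genotype_matrix()] of selected subjects),
#'   `phenotypes` (data frame: sample_id, status, biomarkers, env, age,
#'   smoke, pc1, pc2), and `truth`.
#' @export
simulate_cohort <- function(config, cohort = 1, causal_snps = NULL,
                            gxe_snps = NULL, quant_architecture = NULL,
                            seed = config$seed + cohort) {
  stopifnot(inherits(config, "sim_config"), cohort %in% 1:2)
  set.seed(seed)
  n_target <- config$n_cases_per_cohort[cohort] +
    config$n_controls_per_cohort[cohort]
  n_pool <- ceiling(config$pool_factor * n_target)
  pool <- simulate_genotypes(config, n_pool, seed = NULL)
  if (is.null(causal_snps)) {
    causal_snps <- pick_causal(pool, config$n_causal_binary)
  }
  main_logit <- rep(0, n_pool)
  if (length(causal_snps) > 0 && config$or_causal != 1) {
    main_logit <- drop(dosage_filled(pool, causal_snps) %*%
                         rep(log(config$or_causal), length(causal_snps)))
  }
  if (config$gxe_snp_count > 0 || !is.null(gxe_snps)) {
    sim <- simulate_environment_with_interaction(
      pool, config, cohort, main_logit = main_logit, gxe_snps = gxe_snps,
      exclude = causal_snps)
    env <- sim$env[sim$selected]
    gxe_snps <- sim$gxe_snps
  } else {
    sim <- simulate_binary_trait(pool, config, cohort,
                                 causal_snps = causal_snps,
                                 covariate_logit = NULL)
    sim$causal <- NULL
    env <- stats::rnorm(n_target)
    gxe_snps <- character(0)
  }
  gm <- subset_genotypes(pool, samples = sim$selected)
  attr(gm, "block_id") <- attr(pool, "block_id")
  status <- sim$status
  qt <- simulate_quantitative_traits(gm, config, seed = NULL,
                                     architecture = quant_architecture)
  n <- nrow(gm$calls)
  cohort_age <- if (cohort == 1) 60 else 64.3   # female / male cohort means
  pheno <- data.frame(
    sample_id = rownames(gm$calls),
    status = status,
    qt$traits,
    alcohol = env,
    age = stats::rnorm(n, cohort_age, 7) + 0.3 * status,
    smoke = stats::rbinom(n, 1L, ifelse(status == 1, 0.12, 0.09)),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
    stringsAsFactors = FALSE)
  list(genotypes = gm, phenotypes = pheno,
       truth = list(causal_binary = causal_snps,
                    log_or = log(config$or_causal),
                    quant = qt$truth, gxe_snps = gxe_snps))
}

#' Simulate the full two-cohort study
#'
#' Two cohorts share the SNP panel, the disease-causal SNPs, the interaction
#' SNPs and the gene-set structure (drawn once from the study seed); subjects
#' and biomarker noise are cohort-specific. Sample ids are prefixed by the
#' cohort label so the pooled tables stay unambiguous.
#'
#' @param config A [sim_config()].
#' @param cohort_labels Labels for the two cohorts.
#' @return List: `cohorts` (named list of [simulate_cohort()] outputs),
#'   `gene_sets`, `esnp_map`, `truth` (study-level truth record).
#' @export
simulate_study <- function(config, cohort_labels = c("cohort1", "cohort2")) {
  stopifnot(inherits(config, "sim_config"), length(cohort_labels) == 2)
  set.seed(config$seed)
  # architecture draw: one genotype template fixes SNP panel + causal sets
  template <- simulate_genotypes(config, 50, seed = NULL)
  causal <- pick_causal(template, config$n_causal_binary)
  gxe <- if (config$gxe_snp_count > 0) {
    pick_causal(template, config$gxe_snp_count, exclude = causal,
                min_maf = 0.2)
  } else character(0)
  gs <- simulate_gene_sets_and_esnp_map(
    config, template$snp_meta$id, causal_snps = causal,
    block_id = attr(template, "block_id"), seed = NULL)
  quant_arch <- draw_quant_architecture(config, template, seed = NULL)
  cohorts <- list()
  for (k in 1:2) {
    co <- simulate_cohort(config, k, causal_snps = causal, gxe_snps = gxe,
                          quant_architecture = quant_arch,
                          seed = config$seed + k)
    rownames(co$genotypes$calls) <- paste0(cohort_labels[k], "_",
                                           rownames(co$genotypes$calls))
    co$phenotypes$sample_id <- rownames(co$genotypes$calls)
    cohorts[[cohort_labels[k]]] <- co
  }
  list(cohorts = cohorts, gene_sets = gs$sets, esnp_map = gs$esnp_map,
       truth = list(causal_binary = causal, gxe_snps = gxe,
                    enriched_sets = gs$enriched_sets,
                    log_or = log(config$or_causal),
                    quant_architecture = quant_arch))
}

#' Write a simulated study to disk
#'
#' One VCF and one phenotype TSV per cohort, a GMT for the gene sets, a TSV
#' eSNP map, and a JSON truth record.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$cohorts)) {
    co <- study$cohorts[[nm]]
    write_vcf_gt(co$genotypes, file.path(dir, paste0(nm, ".vcf")))
    write_phenotypes(co$phenotypes, file.path(dir, paste0(nm, ".pheno.tsv")))
  }
  write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(study$esnp_map, file.path(dir, "esnp_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Pool the two cohorts of a simulated study
#'
#' Stacks genotypes and phenotypes (the SNP panel is shared), adding a
#' `cohort` column to the phenotype table.
#'
#' @param study Output of [simulate_study()].
#' @return List: `genotypes`, `phenotypes`.
#' @export
pool_cohorts <- function(study) {
  labs <- names(study$cohorts)
  g1 <- study$cohorts[[1]]$genotypes
  g2 <- study$cohorts[[2]]$genotypes
  stopifnot(identical(g1$snp_meta$id, g2$snp_meta$id))
  gm <- genotype_matrix(rbind(g1$calls, g2$calls), g1$snp_meta)
  ph1 <- study$cohorts[[1]]$phenotypes
  ph2 <- study$cohorts[[2]]$phenotypes
  ph1$cohort <- labs[1]
  ph2$cohort <- labs[2]
  list(genotypes = gm, phenotypes = rbind(ph1, ph2))
}

#' Draw a study-level biomarker architecture
#'
#' Chooses, per biomarker, `n_causal_quant` causal SNPs (at most one per LD
#' block, disjoint across traits while capacity allows) with per-allele
#' effects of magnitude `beta_quant` and random sign. Passed to
#' [simulate_quantitative_traits()] so that both cohorts of a study share
#' one biomarker genetic architecture.
#'
#' @param config A [sim_config()].
#' @param gm A template [genotype_matrix()] carrying the SNP panel.
#' @param seed Optional integer seed.
#' @return Data frame: `trait`, `snp_id`, `beta`.
#' @export
draw_quant_architecture <- function(config, gm, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(gm, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  trait_names <- c("ldl", "hdl", "apob", "tg", "adiponectin", "crp", "tc")
  out <- list()
  used <- character(0)
  for (tr in trait_names) {
    k <- config$n_causal_quant
    if (k == 0) next
    snps <- tryCatch(pick_causal(gm, k, exclude = used),
                     error = function(e) pick_causal(gm, k))
    used <- c(used, snps)
    out[[tr]] <- data.frame(
      trait = tr, snp_id = snps,
      beta = config$beta_quant * sample(c(-1, 1), length(snps), TRUE),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(trait = character(0), snp_id = character(0),
                      beta = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
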