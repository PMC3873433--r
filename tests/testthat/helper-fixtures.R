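# Shared fixtures, built in code. Small study objects are cached per test
# run so several test files can reuse them without re-simulating.

small_config <- function(...) {
  sim_config(n_cases_per_cohort = 100, n_controls_per_cohort = 200,
             n_snps = 600, n_causal_binary = 8, n_causal_quant = 8,
             n_gene_sets = 20, genes_per_set = 4, esnps_per_gene = 5,
             enriched_set_fraction = 0.1, gxe_snp_count = 1,
             missing_rate = 0.01, seed = 11, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- simulate_study(small_config())
  }
  .fixture_cache$study
}

# A tiny deterministic genotype matrix for I/O and QC edge cases.
toy_gm <- function(calls, chrom = NULL, pos = NULL) {
  n_snp <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("chr1", n_snp)
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000L
  genotype_matrix(calls,
                  data.frame(id = paste0("rs", seq_len(n_snp)),
                             chrom = chrom, pos = pos,
                             ref = "A", alt = "B",
                             stringsAsFactors = FALSE))
}

# Independent logistic log-likelihood used by brute-force oracles.
logit_loglik <- function(par, x, y) {
  eta <- par[1] + par[2] * x
  sum(y * eta - log1p(exp(eta)))
}
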