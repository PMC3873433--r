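#!/usr/bin/env Rscript
# Two-cohort meta-analysis per trait: sample-size-weighted signed-z and
# fixed-effects inverse-variance combination; tier the combined results.

source(file.path("analysis", "common.R"))

st <- get_study()
meta <- get_meta(st)

tiered <- do.call(rbind, lapply(names(meta), function(tr) {
  m <- meta[[tr]]
  m$p <- m$p_meta
  head(classify_hits(m), 5)
}))
write_result(tiered, "04_meta_top_hits.tsv")

causal_rank <- lapply(c("mi"), function(tr) {
  m <- meta[[tr]]
  r <- rank(m$p_meta)[match(st$truth$causal_binary, m$snp_id)]
  data.frame(trait = tr, snp_id = st$truth$causal_binary,
             p_rank = r[!is.na(r)][seq_along(st$truth$causal_binary)])
})
write_result(do.call(rbind, causal_rank), "04_truth_snp_ranks.tsv")

n_gw <- sum(tiered$tier == "genome_wide")
n_sg <- sum(tiered$tier == "suggestive")
message(sprintf(
  "Meta-analysis of %d traits: %d genome-wide and %d suggestive rows among the per-trait top 5.",
  length(meta), n_gw, n_sg))
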