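# Risk-score construction and evaluation: greedy 100 kb pruning, the
# +1/0/-1 allele-count scoring with protective-trait sign reversal,
# additivity and recoding invariances.

cand <- function(pos, p, chrom = "chr1", effect = 1) {
  data.frame(snp_id = paste0("rs", seq_along(pos)), chrom = chrom,
             pos = as.integer(pos), reference_allele = "B",
             effect = effect, z = effect, p = p, trait = "ldl",
             stringsAsFactors = FALSE)
}

test_that("greedy pruning measures distance to kept SNPs only", {
  res <- cand(pos = c(100000, 150000, 250000), p = c(1e-8, 1e-6, 1e-7))
  set <- select_score_alleles(res, n_top = 3)
  # 150 kb candidate is 50 kb from the kept 100 kb SNP and is dropped;
  # 250 kb is checked against kept SNPs only and survives
  expect_setequal(set$pos, c(100000, 250000))
  # boundary: exactly 100 kb apart is kept ("at least 100 kb")
  res2 <- cand(pos = c(100000, 200000), p = c(1e-8, 1e-6))
  expect_identical(nrow(select_score_alleles(res2, 2)), 2L)
  # distinct chromosomes: no pruning, top N by p
  res3 <- cand(pos = rep(100000, 4), p = c(0.04, 0.01, 0.03, 0.02),
               chrom = paste0("chr", 1:4))
  set3 <- select_score_alleles(res3, 3)
  expect_identical(nrow(set3), 3L)
  expect_true(all(diff(set3$p) >= 0))
  expect_error(select_score_alleles(res, 0), "positive")
})

test_that("pruned sets always satisfy the pairwise 100 kb invariant", {
  set.seed(50)
  for (i in 1:10) {
    res <- cand(pos = sample(seq(1e5, 3e6, 2.5e4), 60),
                p = runif(60), chrom = sample(paste0("chr", 1:3), 60, TRUE))
    set <- select_score_alleles(res, 25)
    for (ch in unique(set$chrom)) {
      pp <- set$pos[set$chrom == ch]
      if (length(pp) > 1) {
        expect_true(all(abs(outer(pp, pp, "-"))[upper.tri(diag(length(pp)))]
                        >= 1e5))
      }
    }
    expect_true(all(diff(set$p) >= 0))
  }
})

test_that("scoring follows the +1/0/-1 rule with HDL/adiponectin reversal", {
  gm <- toy_gm(matrix(c(2L, 0L, 1L, NA), ncol = 1), pos = 100000L)
  gm$snp_meta$id <- "rs1"
  raising <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 100000L,
                        scored_allele = "counted", sign = 1, trait = "ldl",
                        p = 1e-8)
  # homozygous raising allele: +1; homozygous other: -1; het/missing: 0
  expect_identical(unname(score_subjects(gm, raising)), c(1L, -1L, 0L, 0L))
  hdl <- transform(raising, sign = -1, trait = "hdl")
  expect_identical(unname(score_subjects(gm, hdl)), c(-1L, 1L, 0L, 0L))
  # trait-raising allele is the non-counted one: contributions flip
  other <- transform(raising, scored_allele = "other")
  expect_identical(unname(score_subjects(gm, other)), c(-1L, 1L, 0L, 0L))
})

test_that("select_score_alleles orients the scored allele by effect sign", {
  res <- cand(pos = c(100000, 300000), p = c(1e-8, 1e-7),
              effect = c(0.5, -0.5))
  set <- select_score_alleles(res, 2)
  expect_identical(set$scored_allele, c("counted", "other"))
  # sign conventions by trait
  expect_identical(unname(select_score_alleles(
    transform(res, trait = "hdl"), 2, trait = "hdl")$sign), c(-1, -1))
  expect_identical(unname(select_score_alleles(
    transform(res, trait = "crp"), 2, trait = "crp")$sign), c(1, 1))
})

test_that("scores are additive over a partition of the entry list", {
  set.seed(51)
  gm <- toy_gm(matrix(rbinom(200, 2, 0.4), 10, 20),
               pos = seq(1e5, by = 2e5, length.out = 20))
  res <- data.frame(snp_id = gm$snp_meta$id, chrom = "chr1",
                    pos = gm$snp_meta$pos, reference_allele = "B",
                    effect = rnorm(20), z = rnorm(20),
                    p = runif(20), trait = "ldl")
  set <- select_score_alleles(res, 20)
  total <- score_subjects(gm, set)
  part <- score_subjects(gm, set[1:7, ]) + score_subjects(gm, set[8:20, ])
  expect_identical(total, part)
  # recoding an entry to the opposite allele with flipped sign is a no-op
  rec <- set
  rec$scored_allele[3] <- ifelse(set$scored_allele[3] == "counted",
                                 "other", "counted")
  rec$sign[3] <- -rec$sign[3]
  expect_identical(score_subjects(gm, rec), total)
})

test_that("evaluate_score runs a logistic fit and validates input", {
  set.seed(52)
  score <- rbinom(400, 10, 0.5) - 5
  y <- rbinom(400, 1, plogis(-0.7 + 0.25 * score))
  ev <- evaluate_score(score, y)
  expect_lt(abs(ev$effect - 0.25), 3 * ev$se)
  expect_error(evaluate_score(rep(1, 10), rep(c(0, 1), 5)), "constant")
  expect_error(evaluate_score(rnorm(10), rep(1, 10)), "single class")
  # independent score: null
  ps <- replicate(40, evaluate_score(sample(score), y)$p)
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("merging trait candidate lists deduplicates by smaller p", {
  a <- cand(pos = c(100000, 300000), p = c(1e-6, 1e-5))
  b <- cand(pos = c(100000, 500000), p = c(1e-8, 1e-4))
  b$snp_id <- c("rs1", "rs9")
  b$trait <- "hdl"
  merged <- merge_score_candidates(list(ldl = a, hdl = b), n_top = 10)
  expect_identical(nrow(merged), 3L)
  shared <- merged[merged$snp_id == "rs1", ]
  expect_identical(shared$trait, "hdl")   # smaller p wins
  expect_equal(shared$p, 1e-8)
})

test_that("sweep_thresholds returns one row per N and trait set", {
  set.seed(53)
  gm <- toy_gm(matrix(rbinom(3000, 2, 0.4), 150, 20),
               pos = seq(1e5, by = 2e5, length.out = 20))
  res <- data.frame(snp_id = gm$snp_meta$id, chrom = "chr1",
                    pos = gm$snp_meta$pos, reference_allele = "B",
                    effect = rnorm(20), z = rnorm(20), p = runif(20),
                    trait = "ldl")
  y <- rbinom(150, 1, 0.35)
  out <- sweep_thresholds(list(ldl = res), n_grid = c(5, 10), gm = gm,
                          status = y)
  expect_identical(nrow(out), 2L)
  expect_identical(out$n_requested, c(5, 10))
  expect_true(all(out$n_snps <= out$n_requested))
})
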