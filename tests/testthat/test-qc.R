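# SNP/sample filters, HWE, PCA ancestry screening, genomic control.

test_that("HWE chi-square matches hand computation", {
  expect_equal(hwe_test(c(25, 50, 25)), 1, tolerance = 1e-12)
  # (30,40,30): p-hat = 0.5, expected (25,50,25), chi-square = 1+2+1 = 4
  expect_equal(hwe_test(c(30, 40, 30)),
               stats::pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(hwe_test(c(30, 40, 30)), 0.0455, tolerance = 1e-3)
  expect_equal(hwe_test(c(100, 0, 0)), 1)
  expect_error(hwe_test(c(0, 0, 0)), "zero")
})

test_that("snp_filters annotates every failing rule without short-circuit", {
  set.seed(1)
  n <- 100
  calls <- cbind(
    good = rbinom(n, 2, 0.3),
    high_missing = {
      g <- rbinom(n, 2, 0.3); g[1:3] <- NA; g           # 3% missing
    },
    all_het = rep(1L, n),                               # HWE chi-square = n
    mono = rep(0L, n),
    rare = c(1L, rep(0L, n - 1))                        # maf 0.005
  )
  rep_ <- snp_filters(toy_gm(calls))
  expect_true(rep_$kept[1])
  expect_match(rep_$fail_reasons[2], "call_rate")
  # all heterozygotes: maf 0.5 passes, HWE fails hard
  expect_equal(rep_$maf[3], 0.5)
  expect_lt(rep_$hwe_p[3], 1e-4)
  expect_identical(rep_$fail_reasons[3], "hwe")
  expect_identical(rep_$fail_reasons[4], "monomorphic")
  expect_equal(rep_$hwe_p[4], 1)
  expect_match(rep_$fail_reasons[5], "maf")
  expect_identical(rep_$kept, !nzchar(rep_$fail_reasons))
})

test_that("sample filters flag low call rate and one member of a duplicate pair", {
  set.seed(2)
  calls <- matrix(rbinom(50 * 20, 2, 0.4), 50, 20)
  calls[1, 1] <- NA                  # 95% call rate for sample 1
  calls[2, ] <- calls[3, ]           # duplicates; equal call rates
  gm <- toy_gm(calls)
  rep_ <- sample_filters(gm)
  expect_match(rep_$fail_reasons[1], "call_rate")
  dup_flagged <- grepl("duplicate", rep_$fail_reasons[2:3])
  expect_identical(sum(dup_flagged), 1L)
  # clean matrix: everyone kept
  clean <- toy_gm(matrix(rbinom(30 * 20, 2, 0.4), 30, 20))
  expect_true(all(sample_filters(clean)$kept))
})

test_that("PCA ancestry screen flags a divergent minority population", {
  set.seed(3)
  n_main <- 190; n_min <- 10; n_snp <- 150
  p_main <- runif(n_snp, 0.2, 0.5)
  p_min <- pmin(0.95, p_main + 0.4)   # strongly divergent MAFs
  calls <- rbind(
    sapply(p_main, function(p) rbinom(n_main, 2, p)),
    sapply(p_min, function(p) rbinom(n_min, 2, p)))
  gm <- toy_gm(calls)
  pca <- pca_ancestry(gm, n_components = 2, sd_threshold = 3)
  expect_true(all(!pca$keep[n_main + seq_len(n_min)]))
  # infinite threshold keeps everyone
  expect_true(all(pca_ancestry(gm, 2, sd_threshold = Inf)$keep))
})

test_that("homogeneous population loses at most a sliver to the 3-SD rule", {
  set.seed(4)
  calls <- sapply(runif(200, 0.1, 0.5), function(p) rbinom(400, 2, p))
  pca <- pca_ancestry(toy_gm(calls), 2, sd_threshold = 3)
  expect_lte(mean(!pca$keep), 0.025)
  expect_error(pca_ancestry(toy_gm(calls[1:1, , drop = FALSE]), 2),
               "fewer samples")
})

test_that("genomic control lambda and adjustment follow the median rule", {
  z <- rep(sqrt(0.9098728), 200) * rep(c(-1, 1), 100)
  lam <- genomic_control(z)
  expect_equal(lam, 2, tolerance = 1e-6)
  expect_equal(gc_adjust(z, lam), z / sqrt(2))
  # no deflation below 1, monotone and sign-preserving
  expect_identical(gc_adjust(z, 0.9), z)
  set.seed(5)
  znull <- rnorm(1e5)
  expect_equal(genomic_control(znull), 1, tolerance = 0.02)
  expect_error(genomic_control(numeric(0)), "no z-scores")
  expect_warning(genomic_control(rnorm(10)), "fewer than 100")
})

test_that("filters are order-independent and apply_qc composes them", {
  st <- cached_study()
  gm <- st$cohorts[[1]]$genotypes
  qc <- apply_qc(gm, check_duplicates = FALSE)
  # kept set equals the conjunction of individually applied rules
  r <- qc$snp_report
  manual <- r$call_rate > 0.98 & r$maf >= 0.02 & r$maf > 0 &
    (is.na(r$hwe_p) | r$hwe_p >= 1e-4)
  expect_identical(r$kept, unname(manual))
  expect_equal(ncol(qc$genotypes$calls), sum(r$kept))
})

test_that("distance thinning returns a pairwise-separated subset", {
  meta <- data.frame(id = paste0("s", 1:6), chrom = c(rep("chr1", 4), "chr2", "chr2"),
                     pos = c(1e5, 1.4e5, 2.1e5, 3.2e5, 1e5, 2.5e5))
  kept <- thin_by_distance(meta, 1e5)
  km <- meta[meta$id %in% kept, ]
  for (ch in unique(km$chrom)) {
    p <- sort(km$pos[km$chrom == ch])
    if (length(p) > 1) expect_true(all(diff(p) >= 1e5))
  }
  expect_true("s1" %in% kept)
})
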