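# SNP-set enrichment: KS statistic oracles, mapping and thinning rules,
# permutation/asymptotic agreement, ordering invariance.

test_that("one-sample KS statistic matches step-function enumeration", {
  res <- ks_enrichment(c(0.01, 0.02, 0.03))
  # sup over jumps of i/n - x_(i): max(1/3-.01, 2/3-.02, 1-.03) = 0.97
  expect_equal(res$ks_statistic, 0.97, tolerance = 1e-12)
  expect_identical(res$method, "one_sample")
})

test_that("two-sample D+ matches a brute-force sup over the union grid", {
  set.seed(30)
  for (i in 1:20) {
    x <- runif(sample(5:40, 1))
    y <- runif(sample(50:200, 1))
    res <- ks_enrichment(x, y, perm_below = 0)
    fx <- stats::ecdf(x); fy <- stats::ecdf(y)
    grid <- sort(c(x, y))
    d_brute <- max(fx(grid) - fy(grid))
    expect_equal(res$ks_statistic, d_brute, tolerance = 1e-12)
  }
})

test_that("set and background from the same distribution give vanishing D", {
  set.seed(31)
  x <- runif(1000); y <- runif(1000)
  expect_lt(ks_enrichment(x, y, perm_below = 0)$ks_statistic, 0.08)
})

test_that("input validation of p-value sets", {
  expect_error(ks_enrichment(numeric(0)), "empty")
  expect_error(ks_enrichment(c(0.5, 0)), "0, 1")
  expect_error(ks_enrichment(runif(50), runif(10)), "background smaller")
})

test_that("permutation p agrees with asymptotic p for sets of 50+ on null data", {
  set.seed(32)
  x <- runif(60); y <- runif(1200)
  asym <- ks_enrichment(x, y, perm_below = 0)$ks_p
  perm <- ks_enrichment(x, y, perm_below = 100, n_perm = 4000, seed = 9)$ks_p
  mc_sd <- sqrt(perm * (1 - perm) / 4000)
  expect_lt(abs(asym - perm), max(4 * mc_sd, 0.02))
})

test_that("permutation p is seeded and reproducible", {
  set.seed(33)
  x <- runif(10, 0, 0.5); y <- runif(300)
  p1 <- ks_enrichment(x, y, n_perm = 2000, seed = 4)$ks_p
  p2 <- ks_enrichment(x, y, n_perm = 2000, seed = 4)$ks_p
  expect_identical(p1, p2)
})

test_that("gene sets map to eSNP unions without double counting", {
  map <- data.frame(gene_id = c("g1", "g1", "g2", "g2", "g3", "g3", "g4"),
                    snp_id = c("s1", "s2", "s3", "s4", "s5", "s6", "s2"),
                    tissue_label = "t")
  res <- data.frame(snp_id = paste0("s", 1:6), chrom = "chr1",
                    pos = 1:6 * 1000L, p = seq(0.1, 0.6, 0.1))
  expect_setequal(map_set_to_snps(c("g1", "g2", "g3"), map, res),
                  paste0("s", 1:6))
  # shared eSNP appears once
  expect_setequal(map_set_to_snps(c("g1", "g4"), map, res), c("s1", "s2"))
  # intersection with available results
  res2 <- res[res$snp_id != "s6", ]
  expect_setequal(map_set_to_snps("g3", map, res2), "s5")
})

test_that("distance thinning keeps the smallest p within a window", {
  map <- data.frame(gene_id = "g1", snp_id = c("s1", "s2", "s3"),
                    tissue_label = "t")
  res <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "chr1",
                    pos = c(100000L, 125000L, 150000L),
                    p = c(0.2, 0.01, 0.4))
  expect_identical(map_set_to_snps("g1", map, res, ld_thin_distance = 1e5),
                   "s2")
})

test_that("run_ssea is invariant to set order and handles small inputs", {
  set.seed(34)
  snps <- paste0("s", 1:200)
  res <- data.frame(snp_id = snps, chrom = "chr1", pos = 1:200 * 1000L,
                    p = runif(200))
  map <- data.frame(gene_id = rep(paste0("g", 1:40), each = 5),
                    snp_id = snps, tissue_label = "t")
  sets <- lapply(1:8, function(i) paste0("g", (i - 1) * 5 + 1:5))
  names(sets) <- paste0("set", 1:8)
  out1 <- run_ssea(sets, map, res, perm_below = 0)
  out2 <- run_ssea(rev(sets), map, res, perm_below = 0)
  expect_equal(out1, out2, ignore_attr = TRUE)
  expect_identical(nrow(run_ssea(sets[1], map, res, perm_below = 0)), 1L)
  expect_error(run_ssea(list(), map, res), "empty")
  # a set below the size floor is skipped with a reason
  small <- c(sets, list(tiny = "g_unmapped"))
  out3 <- run_ssea(small, map, res, perm_below = 0)
  expect_false("tiny" %in% out3$set)
  expect_match(attr(out3, "skipped")[["tiny"]], "mapped to 0")
})

test_that("disjoint null sets give uniform enrichment p-values", {
  set.seed(35)
  ps <- replicate(300, {
    x <- runif(30); y <- runif(600)
    ks_enrichment(x, y, perm_below = 0)$ks_p
  })
  # one-sided asymptotic p under the null: roughly uniform (the asymptotic
  # p-value is discrete at these set sizes, hence suppressed ties warning)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("QQ export writes one sorted two-column table per set", {
  set.seed(36)
  snps <- paste0("s", 1:60)
  res <- data.frame(snp_id = snps, chrom = "chr1", pos = 1:60 * 1000L,
                    p = runif(60))
  map <- data.frame(gene_id = rep(c("g1", "g2"), each = 30), snp_id = snps,
                    tissue_label = "t")
  out <- run_ssea(list(a = "g1", b = "g2"), map, res, perm_below = 0)
  dir <- withr::local_tempdir()
  write_qq_data(out, dir)
  qq <- utils::read.delim(file.path(dir, "a.qq.tsv"))
  expect_identical(names(qq), c("expected", "observed"))
  expect_identical(nrow(qq), 30L)
  expect_true(all(diff(qq$observed) <= 0))
})
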