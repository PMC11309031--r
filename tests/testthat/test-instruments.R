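test_that("p-value selection is strict and errors when nothing survives", {
  tab <- make_stats(n = 3, pval = c(1e-9, 5e-8, 1e-7))
  sel <- selectByPvalue(tab, 5e-8)
  expect_equal(variants(sel)$snp_id, "rs1")  # strict <: 5e-8 itself excluded
  expect_equal(nVariants(selectByPvalue(tab, 1)), 3L)
  flat <- make_stats(n = 3, pval = 0.5)
  expect_error(selectByPvalue(flat, 5e-8), "5e-08")
})

test_that("greedy clumping keeps the most significant of linked nearby SNPs", {
  tab <- make_stats(n = 2, pos_bp = c(1e6, 1e6 + 1000),
                    pval = c(1e-9, 1e-10))
  ld <- ldTable(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5))
  kept <- greedyClump(tab, ld)
  expect_equal(variants(kept)$snp_id, "rs2")  # the p = 1e-10 SNP

  ld_lo <- ldTable(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.0005))
  expect_equal(nVariants(greedyClump(tab, ld_lo)), 2L)  # below threshold
})

test_that("clumping needs positions when a window is requested", {
  v <- variant_df(2)
  v$pos_bp <- NA_integer_
  expect_error(greedyClump(summaryStats(v, "x")), "pos_bp")
})

test_that("clumping on chained-LD instances matches the step-by-step oracle", {
  for (seed in c(101, 202, 303)) {
    set.seed(seed)
    n <- 8
    v <- variant_df(n, chrom = sample(c("1", "2"), n, replace = TRUE),
                    pos_bp = sample.int(3e7, n),
                    pval = 10^-runif(n, 6, 12))
    pairs <- t(utils::combn(n, 2))
    take <- sample(c(TRUE, FALSE), nrow(pairs), replace = TRUE)
    ld_df <- data.frame(snp_a = v$snp_id[pairs[take, 1]],
                        snp_b = v$snp_id[pairs[take, 2]],
                        r2 = runif(sum(take)))
    cfg <- selectionConfig(clumpR2 = 0.3, clumpWindowKb = 10000)
    got <- variants(greedyClump(summaryStats(v, "x"), ldTable(ld_df), cfg))$snp_id
    expect_equal(got, oracle_clump(v, ld_df, 0.3, 10000))
  }
})

test_that("the clumped set is independent and invariant to row permutation", {
  set.seed(77)
  n <- 10
  v <- variant_df(n, chrom = "1", pos_bp = sort(sample.int(2e7, n)),
                  pval = 10^-runif(n, 6, 12))
  pairs <- t(utils::combn(n, 2))
  ld_df <- data.frame(snp_a = v$snp_id[pairs[, 1]],
                      snp_b = v$snp_id[pairs[, 2]],
                      r2 = runif(nrow(pairs)))
  ld <- ldTable(ld_df)
  cfg <- selectionConfig(clumpR2 = 0.4, clumpWindowKb = 5000)
  kept <- variants(greedyClump(summaryStats(v, "x"), ld, cfg))
  # independence: no retained pair is both within window and >= r2 threshold
  if (nrow(kept) > 1) {
    for (i in seq_len(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
      within <- kept$chrom[i] == kept$chrom[j] &&
        abs(kept$pos_bp[i] - kept$pos_bp[j]) <= 5e6
      r2 <- mrmediate:::.ld_r2(ld, kept$snp_id[i], kept$snp_id[j])
      expect_false(within && r2 >= 0.4)
    }
  }
  perm <- v[sample.int(n), ]
  kept_perm <- variants(greedyClump(summaryStats(perm, "x"), ld, cfg))
  expect_setequal(kept_perm$snp_id, kept$snp_id)
})

test_that("variance explained follows 2 beta^2 EAF (1-EAF) and its symmetries", {
  expect_equal(varianceExplained(0.1, 0.5), 0.005)
  expect_equal(varianceExplained(0.2, 0.25), 0.015)
  expect_equal(varianceExplained(0.3, 0), 0)
  # symmetric in eaf -> 1 - eaf; maximal at 0.5
  eafs <- seq(0.05, 0.95, by = 0.05)
  expect_equal(varianceExplained(0.2, eafs), varianceExplained(0.2, 1 - eafs))
  expect_true(all(varianceExplained(0.2, 0.5) >=
                    varianceExplained(0.2, eafs)))
  expect_error(varianceExplained(0.1, NA, snp_id = "rs9"), "rs9")
})

test_that("the F-statistic formula, monotonicity and domain errors hold", {
  expect_equal(fStatistic(0.01, 1002, 1), 10.1010101010101)
  expect_equal(fStatistic(0, 100, 1), 0)
  expect_equal(fStatistic(0.1, 101, 10), 1)
  # strictly increasing in r2 and n
  expect_true(all(diff(fStatistic(seq(0.001, 0.5, by = 0.01), 1000, 1)) > 0))
  expect_true(all(diff(fStatistic(0.01, seq(100, 5000, by = 100), 1)) > 0))
  expect_error(fStatistic(0.1, 11, 10), "exceed")
})

test_that("weak instruments are excluded strictly below the F cutoff", {
  # per-SNP F = (n-2) r2/(1-r2); pick betas giving F just below / above 10
  r2_for_f <- function(f, n) f / (n - 2 + f)
  n <- 10000
  r2 <- r2_for_f(c(9.9, 10.0, 25), n)
  beta <- sqrt(r2 / (2 * 0.5 * 0.5))
  tab <- make_stats(n = 3, beta = beta, eaf = 0.5, n_col = n)
  kept <- filterWeak(tab, 10)
  expect_equal(variants(kept)$snp_id, c("rs2", "rs3"))  # 9.9 dropped, 10 kept
  expect_equal(attr(kept, "dropped"), "rs1")
  strong <- filterWeak(make_stats(n = 3, beta = 0.2, eaf = 0.5, n_col = n))
  expect_equal(nVariants(strong), 3L)
  weak <- make_stats(n = 3, beta = 1e-4, eaf = 0.5, n_col = n)
  expect_error(filterWeak(weak), "empty instrument")
})

test_that("instrument strength reports per-SNP and joint quantities", {
  tab <- make_stats(n = 2, beta = c(0.1, 0.2), eaf = 0.5, n_col = 1002)
  s <- instrumentStrength(tab)
  expect_equal(unname(s$r2PerSnp), c(0.005, 0.02))
  expect_equal(s$r2Total, 0.025)
  expect_equal(s$K, 2L)
  expect_equal(unname(s$fPerSnp[1]), fStatistic(0.005, 1002, 1))
  expect_equal(s$fJoint, fStatistic(0.025, 1002, 2))
})

test_that("LD tables read from TSV and default absent pairs to zero", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- readLDTable(path)
  expect_equal(mrmediate:::.ld_r2(ld, "rs1", c("rs2", "rs3", "rs1")),
               c(0.9, 0, 1))
})
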