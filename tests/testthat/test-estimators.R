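test_that("Wald ratios follow first-order arithmetic and sign symmetry", {
  r <- waldRatio(0.5, 0.05, 0.4, 0.1)
  expect_equal(r$ratio, 0.8)
  expect_equal(r$se_ratio, 0.2)
  expect_equal(waldRatio(0.5, 0.05, 0, 0.1)$ratio, 0)
  # joint sign flip leaves the ratio unchanged
  expect_equal(waldRatio(-0.5, 0.05, -0.4, 0.1)$ratio, 0.8)
  expect_error(waldRatio(0, 0.05, 0.4, 0.1), "degenerate")
})

test_that("IVW with one pair reduces exactly to the Wald ratio", {
  h <- hset_from(0.5, 0.05, 0.4, 0.1)
  est <- mrIVW(h)
  expect_equal(est@method, "Wald ratio")
  expect_equal(est@beta, 0.8)
  expect_equal(est@se, 0.2)
})

test_that("identical per-SNP ratios engage the overdispersion floor", {
  h <- hset_from(c(0.2, 0.4, 0.5), 0.02, c(0.1, 0.2, 0.25), c(0.05, 0.06, 0.04))
  est <- mrIVW(h)
  expect_equal(est@beta, 0.5)
  expect_equal(est@scalePhi, 0, tolerance = 1e-12)
  w <- 1 / c(0.05, 0.06, 0.04)^2
  expect_equal(est@se, 1 / sqrt(sum(w * c(0.2, 0.4, 0.5)^2)))  # fixed-effect SE
})

test_that("IVW and Egger match the weighted-least-squares oracle to 1e-10", {
  set.seed(42)
  for (rep in 1:5) {
    J <- sample(4:12, 1)
    bx <- rnorm(J, 0.05, 0.02)
    by <- rnorm(J, 0.8 * bx, 0.03)
    sy <- runif(J, 0.02, 0.08)
    h <- hset_from(bx, 0.01, by, sy)

    ow <- oracle_wls_origin(bx, by, sy)
    est <- mrIVW(h)
    expect_equal(est@beta, ow$beta, tolerance = 1e-10)
    expect_equal(est@se, ow$se, tolerance = 1e-10)
    expect_equal(est@scalePhi, ow$phi, tolerance = 1e-10)

    s <- sign(bx)
    oe <- oracle_wls_intercept(abs(bx), s * by, sy)
    egg <- mrEgger(h)
    expect_equal(egg@beta, oe$slope, tolerance = 1e-10)
    expect_equal(egg@intercept, oe$intercept, tolerance = 1e-10)
    expect_equal(unname(egg@se), oe$se[2], tolerance = 1e-10)
    expect_equal(unname(egg@interceptSE), oe$se[1], tolerance = 1e-10)
  }
})

test_that("the IVW reported SE is never below the fixed-effect SE", {
  set.seed(7)
  for (rep in 1:20) {
    J <- sample(3:15, 1)
    bx <- rnorm(J, 0.05, 0.02)
    by <- rnorm(J, 0.5 * bx, 0.05)
    sy <- runif(J, 0.01, 0.1)
    est <- mrIVW(hset_from(bx, 0.01, by, sy))
    se_fe <- 1 / sqrt(sum(bx^2 / sy^2))
    expect_gte(est@se, se_fe - 1e-14)
  }
})

test_that("Egger needs three instruments and recovers injected directional pleiotropy", {
  expect_error(mrEgger(hset_from(c(0.1, 0.2), 0.01, c(0.05, 0.1), 0.05)),
               "insufficient")
  # across replicates: zero-pleiotropy intercepts center at 0, and adding a
  # constant alpha to every outcome effect shifts the intercept by alpha
  # while leaving the slope centered on the causal effect
  set.seed(11)
  reps <- 120
  J <- 26
  int0 <- slope0 <- int1 <- slope1 <- numeric(reps)
  alpha <- 0.05
  for (r in seq_len(reps)) {
    gamma <- runif(J, 0.03, 0.06)
    sy <- runif(J, 0.03, 0.05)
    bx <- rnorm(J, gamma, 0.003)
    by <- rnorm(J, 0.79 * gamma, sy)
    e0 <- mrEgger(hset_from(bx, 0.003, by, sy))
    e1 <- mrEgger(hset_from(bx, 0.003, by + alpha, sy))
    int0[r] <- e0@intercept; slope0[r] <- e0@beta
    int1[r] <- e1@intercept; slope1[r] <- e1@beta
  }
  mcse <- function(x) stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(int0)), 2 * mcse(int0))
  expect_lt(abs(mean(int1) - alpha), 2 * mcse(int1))
  expect_lt(abs(mean(slope1) - mean(slope0)), 2 * mcse(slope1 - slope0))
})

test_that("the weighted median interpolates cumulative weight 0.5", {
  # equal weights, odd count: the middle ratio
  h <- hset_from(c(1, 1, 1), 0.01, c(0.2, 0.8, 1.4), 0.05)
  est <- mrWeightedMedian(h, methodConfig(bootstrapB = 100, seed = 1))
  expect_equal(est@beta, 0.8)

  # a SNP with > 50% of total weight dictates the estimate
  h <- hset_from(c(1, 1, 1), 0.01, c(0.2, 0.8, 1.4),
                 c(0.01, 0.2, 0.2))  # first ratio carries ~99% of weight
  est <- mrWeightedMedian(h, methodConfig(bootstrapB = 100, seed = 1))
  expect_equal(est@beta, 0.2)

  # unequal weights: frozen value from the cumulative-weight oracle
  h <- hset_from(rep(1, 4), 0.01, c(0.1, 0.5, 0.9, 1.3),
                 1 / sqrt(c(1, 2, 3, 4)))
  est <- mrWeightedMedian(h, methodConfig(bootstrapB = 100, seed = 1))
  expect_equal(est@beta, 0.957142857142857, tolerance = 1e-12)
  expect_equal(est@beta,
               oracle_weighted_median(c(0.1, 0.5, 0.9, 1.3), c(1, 2, 3, 4)))
})

test_that("equal-weight weighted medians equal the interpolated plain median", {
  set.seed(5)
  for (rep in 1:10) {
    r <- rnorm(sample(3:9, 1))
    h <- hset_from(rep(1, length(r)), 0.01, r, 1)
    est <- mrWeightedMedian(h, methodConfig(bootstrapB = 100, seed = 1))
    expect_equal(est@beta, stats::median(r))
  }
})

test_that("mode-based estimators find the ratio cluster and honor weighting", {
  # degenerate: all ratios equal
  h <- hset_from(c(1, 2, 4), 0.01, 0.7 * c(1, 2, 4), 0.05)
  est <- mrMode(h, cfg = methodConfig(bootstrapB = 100, seed = 1))
  expect_equal(est@beta, 0.7)

  # cluster at 0.80 with one gross outlier: estimate within one bandwidth
  r <- c(0.79, 0.80, 0.81, 5.0)
  h <- hset_from(rep(1, 4), 0.01, r, 0.05)
  est <- mrMode(h, weighted = FALSE, methodConfig(bootstrapB = 100, seed = 1))
  h_bw <- 0.9 * min(stats::sd(r), stats::mad(r)) * 4^(-0.2)
  expect_lt(abs(est@beta - 0.80), h_bw)

  # weighted vs simple differ when the outlying ratio dominates the weight
  h2 <- hset_from(rep(1, 4), 0.01, r, c(0.5, 0.5, 0.5, 0.001))
  w_est <- mrMode(h2, weighted = TRUE, methodConfig(bootstrapB = 100, seed = 1))
  s_est <- mrMode(h2, weighted = FALSE, methodConfig(bootstrapB = 100, seed = 1))
  expect_lt(abs(w_est@beta - 5.0), 0.05)
  expect_lt(abs(s_est@beta - 0.80), 0.05)
})

test_that("the suite returns the five methods in table order, downgrading below 3 SNPs", {
  h <- preset_hxy(3)
  suite <- runMethodSuite(h, methodConfig(bootstrapB = 100, seed = 2))
  expect_equal(names(suite), c("MR Egger", "Weighted median", "IVW",
                               "Simple mode", "Weighted mode"))
  one <- hset_from(0.5, 0.05, 0.4, 0.1)
  expect_message(down <- runMethodSuite(one, methodConfig(seed = 2)),
                 "downgraded")
  expect_equal(names(down), "Wald ratio")
  expect_match(attr(down, "downgrade"), "1 instrument")
})

test_that("fixed seeds make the suite bit-reproducible", {
  h <- preset_hxy(9)
  cfg <- methodConfig(bootstrapB = 150, seed = 77)
  s1 <- runMethodSuite(h, cfg)
  s2 <- runMethodSuite(h, cfg)
  for (m in names(s1)) {
    expect_identical(s1[[m]]@beta, s2[[m]]@beta)
    expect_identical(s1[[m]]@se, s2[[m]]@se)
    expect_identical(s1[[m]]@pval, s2[[m]]@pval)
  }
})

test_that("estimates are invariant to SNP order and joint sign flips", {
  set.seed(12)
  J <- 8
  bx <- rnorm(J, 0.05, 0.01); sx <- rep(0.004, J)
  by <- rnorm(J, 0.8 * bx, 0.04); sy <- runif(J, 0.03, 0.06)
  h <- hset_from(bx, sx, by, sy)
  flip <- rep(c(1, -1), length.out = J)
  perm <- sample.int(J)
  h_t <- hset_from((bx * flip)[perm], sx[perm], (by * flip)[perm], sy[perm],
                   ids = sprintf("rs%d", seq_len(J))[perm])
  cfg <- methodConfig(bootstrapB = 100, seed = 3)
  expect_equal(mrIVW(h_t)@beta, mrIVW(h)@beta)
  expect_equal(mrIVW(h_t)@se, mrIVW(h)@se)
  expect_equal(mrEgger(h_t)@beta, mrEgger(h)@beta)  # via internal orientation
  expect_equal(mrWeightedMedian(h_t, cfg)@beta, mrWeightedMedian(h, cfg)@beta)
  expect_equal(mrMode(h_t, TRUE, cfg)@beta, mrMode(h, TRUE, cfg)@beta)
})

test_that("BH-FDR adjustment matches the manual step-up and is monotone", {
  p <- c(0.022, 0.056, 0.008, 0.005)
  adj <- adjustFDR(p)
  expect_equal(adj, oracle_bh(p))
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in raw p
  expect_equal(adjustFDR(0.03), 0.03)
  expect_equal(adjustFDR(rep(0.2, 5)), rep(0.2, 5))
  expect_identical(adjustFDR(numeric()), numeric())
  # randomized property check against the oracle
  set.seed(4)
  for (rep in 1:10) {
    p <- runif(sample(2:20, 1))
    expect_equal(adjustFDR(p), oracle_bh(p))
  }
})

test_that("mrTable lays estimates out one row per method", {
  h <- preset_hxy(21)
  suite <- runMethodSuite(h, methodConfig(bootstrapB = 100, seed = 5))
  tab <- mrTable(suite, "coffee", "CAC")
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$exposure, rep("coffee", 5))
  expect_true(all(c("method", "nsnp", "beta", "ci_low", "ci_high", "pval")
                  %in% names(tab)))
})
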