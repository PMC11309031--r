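test_that("Cochran's Q is zero for identical ratios and matches manual arithmetic", {
  h <- hset_from(c(0.2, 0.4, 0.5), 0.02, 0.7 * c(0.2, 0.4, 0.5),
                 c(0.05, 0.06, 0.04))
  q <- cochranQ(h, "IVW")
  expect_equal(q@Q, 0, tolerance = 1e-20)
  expect_equal(q@pval, 1)
  expect_equal(q@df, 2L)

  # J = 3 hand-computed instance (weights bx^2/sy^2, fixed-effect center)
  h3 <- hset_from(c(0.1, 0.2, 0.4), 0.01, c(0.08, 0.18, 0.30),
                  c(0.05, 0.08, 0.1))
  q3 <- cochranQ(h3, "IVW")
  expect_equal(q3@Q, 0.101333333333333, tolerance = 1e-12)
  expect_equal(q3@pval, 0.950595482888397, tolerance = 1e-12)
})

test_that("under the null the mean of Q/(J-1) is near one", {
  set.seed(8)
  reps <- 150
  ratio <- numeric(reps)
  for (r in seq_len(reps)) {
    J <- 26
    gamma <- runif(J, 0.03, 0.06)
    sy <- runif(J, 0.03, 0.05)
    # exact exposure effects isolate the chi-square behaviour of Q
    h <- hset_from(gamma, 1e-6, rnorm(J, 0.79 * gamma, sy), sy)
    q <- cochranQ(h, "IVW")
    ratio[r] <- q@Q / q@df
  }
  expect_lt(abs(mean(ratio) - 1), 3 * stats::sd(ratio) / sqrt(reps))
})

test_that("Rucker's Q' vanishes on exact linear fits and never exceeds Cochran's Q", {
  # perfectly collinear with an intercept: by = 0.1 + 0.5 bx
  bx <- c(0.1, 0.2, 0.3, 0.5)
  h <- hset_from(bx, 0.01, 0.1 + 0.5 * bx, 0.05)
  qe <- cochranQ(h, "Egger")
  expect_equal(qe@Q, 0, tolerance = 1e-20)
  expect_equal(qe@df, 2L)

  set.seed(19)
  for (rep in 1:10) {
    J <- sample(4:12, 1)
    bx <- runif(J, 0.02, 0.08)
    sy <- runif(J, 0.02, 0.06)
    by <- rnorm(J, 0.5 * bx + 0.02, sy)
    h <- hset_from(bx, 0.01, by, sy)
    expect_lte(cochranQ(h, "Egger")@Q, cochranQ(h, "IVW")@Q + 1e-12)
  }

  # J = 4 weighted-residual oracle
  bx <- c(0.05, 0.1, 0.2, 0.3); sy <- c(0.03, 0.05, 0.04, 0.06)
  by <- c(0.06, 0.04, 0.15, 0.2)
  h <- hset_from(bx, 0.01, by, sy)
  fit <- oracle_wls_intercept(bx, by, sy)
  q_orc <- sum((by - fit$intercept - fit$slope * bx)^2 / sy^2)
  expect_equal(cochranQ(h, "Egger")@Q, q_orc, tolerance = 1e-10)
})

test_that("Q statistics are invariant to SNP order and joint sign flips", {
  set.seed(23)
  J <- 9
  bx <- rnorm(J, 0.05, 0.01); by <- rnorm(J, 0.6 * bx, 0.05)
  sy <- runif(J, 0.02, 0.07)
  h <- hset_from(bx, 0.01, by, sy)
  flip <- rep(c(1, -1), length.out = J); perm <- sample.int(J)
  h_t <- hset_from((bx * flip)[perm], 0.01, (by * flip)[perm], sy[perm])
  expect_equal(cochranQ(h_t, "IVW")@Q, cochranQ(h, "IVW")@Q)
  expect_equal(cochranQ(h_t, "Egger")@Q, cochranQ(h, "Egger")@Q)
})

test_that("the Egger intercept test mirrors the Egger fit and its df", {
  h <- preset_hxy(13)
  plei <- eggerInterceptTest(h)
  egg <- mrEgger(h)
  expect_equal(plei@intercept, egg@intercept)
  expect_equal(plei@pval, egg@interceptPval)
  expect_equal(plei@df, nPairs(h) - 2L)
  expect_error(eggerInterceptTest(hset_from(c(0.1, 0.2), 0.01,
                                            c(0.1, 0.2), 0.05)),
               "insufficient")
})

test_that("PRESSO p-values respect the Monte-Carlo resolution bound and seeding", {
  h <- preset_hxy(17)
  cfg <- pressoConfig(nbSim = 300, seed = 5)
  res <- mrPresso(h, cfg)
  expect_gte(res@globalPval, 1 / 301)
  expect_true(all(res@outlierPvals >= 1 / 301))
  expect_true(all(names(res@outlierPvals) %in%
                    harmonizedPairs(h)$snp_id))  # flags subset of inputs
  res2 <- mrPresso(h, cfg)
  expect_identical(res@globalPval, res2@globalPval)
  expect_identical(res@outlierPvals, res2@outlierPvals)
  expect_error(mrPresso(hset_from(c(0.1, 0.2, 0.3), 0.01,
                                  c(0.1, 0.2, 0.3), 0.05)),
               "insufficient")
})

test_that("a gross outlier drives the global p to its floor and is the SNP flagged", {
  h <- preset_hxy(29)
  p <- harmonizedPairs(h)
  p$by[4] <- p$by[4] + 10 * p$sy[4]
  h_out <- hset_from(p$bx, p$sx, p$by, p$sy, ids = p$snp_id)
  # nbSim must exceed J / 0.05 for Bonferroni-adjusted flagging to be possible
  res <- mrPresso(h_out, pressoConfig(nbSim = 1000, seed = 6))
  expect_equal(res@globalPval, 1 / 1001)
  expect_equal(res@outliers, p$snp_id[4])
  # distortion ran: removing the outlier moves the estimate toward truth
  expect_false(is.na(res@distortionPval))
  theta_all <- mrIVW(h_out)@beta
  expect_lt(abs(res@corrected@beta - 0.79), abs(theta_all - 0.79))
})

test_that("null data rarely flag outliers at the Bonferroni threshold", {
  set.seed(33)
  flagged <- vapply(1:60, function(r) {
    h <- preset_hxy(6000 + r)
    length(pressoOutliers(h, pressoConfig(nbSim = 1000, seed = r))$outliers)
  }, numeric(1))
  expect_gte(mean(flagged == 0), 0.9)
})

test_that("distortion after removing a non-influential SNP is small with a large p", {
  h <- preset_hxy(41)
  p <- harmonizedPairs(h)
  res <- pressoDistortion(h, outliers = p$snp_id[1],
                          cfg = pressoConfig(nbSim = 300, seed = 9))
  expect_lt(abs(res$distortion), 0.25)
  expect_gt(res$pval, 0.05)
  expect_error(pressoDistortion(h, outliers = p$snp_id[-1],
                                cfg = pressoConfig(nbSim = 100, seed = 9)),
               "degenerate")
})
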