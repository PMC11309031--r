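## Sensitivity analyses: heterogeneity (Cochran's Q under IVW, Rucker's Q'
## under Egger), directional pleiotropy (Egger intercept), and the
## simulation-based MR-PRESSO global / outlier / distortion tests.

#' Heterogeneity tests
#'
#' Under the IVW framework, Cochran's Q over the per-SNP Wald ratios with
#' first-order weights `w_j = bx_j^2 / sy_j^2` about the fixed-effect IVW
#' estimate (J - 1 df). Under the Egger framework, Rucker's Q': the weighted
#' residual sum of squares about the (oriented) Egger fit (J - 2 df). Q' is
#' never larger than Q on the same data (nested models with identical
#' weights). P-values are upper chi-square tails; `p < 0.05` is the
#' conventional signal of heterogeneity.
#'
#' @param hset a [HarmonizedSet-class] (at least 2 pairs for IVW, 3 for
#'   Egger).
#' @param framework `"IVW"` or `"Egger"`.
#' @return a [HeterogeneityResult-class].
#' @export
cochranQ <- function(hset, framework = c("IVW", "Egger")) {
  framework <- match.arg(framework)
  p <- harmonizedPairs(hset)
  J <- nrow(p)
  if (framework == "IVW") {
    if (J < 2L) .stop_insufficient(2L, J, "Cochran's Q")
    w <- p$bx^2 / p$sy^2
    r <- p$by / p$bx
    theta <- sum(w * r) / sum(w)
    Q <- sum(w * (r - theta)^2)
    df <- J - 1L
  } else {
    fit <- .egger_fit(hset)  # errors below 3 pairs
    Q <- fit$rss
    df <- fit$df
  }
  methods::new("HeterogeneityResult", framework = framework, Q = Q,
               df = as.integer(df),
               pval = stats::pchisq(Q, df, lower.tail = FALSE))
}

setMethod("show", "HeterogeneityResult", function(object) {
  cat(sprintf("%s heterogeneity: Q = %.4g on %d df, p = %.3g\n",
              if (object@framework == "IVW") "Cochran's Q (IVW)"
              else "Rucker's Q' (Egger)",
              object@Q, object@df, object@pval))
})

#' Egger-intercept test for directional pleiotropy
#'
#' Reports the intercept of the MR-Egger regression, its standard error and
#' the two-sided t-test p-value (J - 2 df); `p < 0.05` conventionally
#' indicates directional pleiotropy.
#'
#' @param hset a [HarmonizedSet-class] with at least 3 pairs.
#' @return a [PleiotropyResult-class].
#' @export
eggerInterceptTest <- function(hset) {
  fit <- .egger_fit(hset)
  t_int <- fit$coef["intercept"] / fit$se["intercept"]
  methods::new("PleiotropyResult",
               intercept = unname(fit$coef["intercept"]),
               interceptSE = unname(fit$se["intercept"]),
               pval = 2 * stats::pt(-abs(t_int), df = fit$df),
               df = as.integer(fit$df))
}

setMethod("show", "PleiotropyResult", function(object) {
  cat(sprintf("Egger intercept: %.4g (se %.4g), t-test p = %.3g (%d df)\n",
              object@intercept, object@interceptSE, object@pval, object@df))
})

#' MR-PRESSO settings
#'
#' @param nbSim number of simulated datasets for the empirical null
#'   (minimum 100; the global p-value can never fall below
#'   `1 / (nbSim + 1)`).
#' @param seed RNG seed.
#' @param sigThreshold significance threshold for flagging outliers
#'   (applied to Bonferroni-adjusted per-SNP p-values).
#' @return a list of class `pressoConfig`.
#' @export
pressoConfig <- function(nbSim = 1000, seed = 1L, sigThreshold = 0.05) {
  stopifnot(nbSim >= 100, sigThreshold > 0, sigThreshold < 1)
  structure(list(nbSim = as.integer(nbSim), seed = seed,
                 sigThreshold = sigThreshold), class = "pressoConfig")
}

## core PRESSO machinery: observed leave-one-out residual statistics and
## their simulated null distribution.
##   obs_j  = w_j (by_j - theta_loo_j bx_j)^2,  w_j = 1/sy_j^2
##   sims   : nbSim datasets by*_j ~ N(theta_loo_j bx_j, sy_j^2), each
##            rescored with its own leave-one-out estimates
.presso_core <- function(hset, cfg) {
  p <- harmonizedPairs(hset)
  J <- nrow(p)
  if (J < 4L) .stop_insufficient(4L, J, "MR-PRESSO")
  w <- 1 / p$sy^2
  sxy <- sum(w * p$bx * p$by)
  sxx <- sum(w * p$bx^2)
  theta_loo <- (sxy - w * p$bx * p$by) / (sxx - w * p$bx^2)
  obs_j <- w * (p$by - theta_loo * p$bx)^2
  nb <- cfg$nbSim
  sims <- .with_seed(cfg$seed, function() {
    BY <- matrix(stats::rnorm(J * nb, mean = theta_loo * p$bx, sd = p$sy),
                 nrow = J, ncol = nb)
    sxyS <- colSums(w * p$bx * BY)
    THL <- (rep(sxyS, each = J) - w * p$bx * BY) / (sxx - w * p$bx^2)
    w * (BY - THL * p$bx)^2
  })
  list(pairs = p, J = J, obs_j = obs_j, rss_obs = sum(obs_j), sims = sims)
}

#' MR-PRESSO global pleiotropy test
#'
#' Compares the observed residual sum of squares about leave-one-out IVW
#' fits to its distribution over `nbSim` datasets simulated under the
#' no-pleiotropy model. The Monte-Carlo p-value uses the add-one
#' convention, so it is bounded below by `1/(nbSim + 1)`.
#'
#' @param hset a [HarmonizedSet-class] with at least 4 pairs.
#' @param cfg a [pressoConfig()].
#' @return a [PressoResult-class] with the global fields filled (outlier
#'   and distortion fields empty).
#' @export
pressoGlobal <- function(hset, cfg = pressoConfig()) {
  core <- .presso_core(hset, cfg)
  rss_sim <- colSums(core$sims)
  methods::new("PressoResult", rssObs = core$rss_obs,
               globalPval = (1 + sum(rss_sim >= core$rss_obs)) / (cfg$nbSim + 1),
               outlierPvals = stats::setNames(numeric(), character()),
               outliers = character(), nbSim = cfg$nbSim,
               seed = as.numeric(if (is.null(cfg$seed)) NA else cfg$seed))
}

#' MR-PRESSO per-SNP outlier test
#'
#' Each SNP's observed leave-one-out residual statistic is compared to its
#' simulated null distribution; per-SNP Monte-Carlo p-values are
#' Bonferroni-adjusted by the number of SNPs, and SNPs with adjusted
#' `p < sigThreshold` are flagged.
#'
#' @inheritParams pressoGlobal
#' @return list with `pvals` (named, adjusted) and `outliers` (flagged
#'   snp_ids, always a subset of the input SNPs).
#' @export
pressoOutliers <- function(hset, cfg = pressoConfig()) {
  core <- .presso_core(hset, cfg)
  praw <- (1 + rowSums(core$sims >= core$obs_j)) / (cfg$nbSim + 1)
  padj <- stats::setNames(pmin(1, praw * core$J), core$pairs$snp_id)
  list(pvals = padj, outliers = names(padj)[padj < cfg$sigThreshold])
}

#' MR-PRESSO distortion test
#'
#' Removes the flagged outliers, re-estimates by IVW, and reports the
#' relative shift `(theta_all - theta_corrected) / |theta_corrected|`
#' together with a bootstrap p-value obtained by re-estimating after
#' removing random subsets of the same size.
#'
#' @param hset a [HarmonizedSet-class].
#' @param outliers character vector of flagged snp_ids (non-empty).
#' @param cfg a [pressoConfig()].
#' @return list with `distortion`, `pval` and `corrected` (an
#'   [MREstimate-class]); removal leaving fewer than 2 pairs is an error.
#' @export
pressoDistortion <- function(hset, outliers, cfg = pressoConfig()) {
  stopifnot(length(outliers) > 0)
  p <- harmonizedPairs(hset)
  keep <- !(p$snp_id %in% outliers)
  if (sum(keep) < 2L)
    stop("degenerate correction: outlier removal leaves fewer than 2 pairs",
         call. = FALSE)
  sub <- function(rows) .harmonized_set(p$snp_id[rows], p$bx[rows], p$sx[rows],
                                        p$by[rows], p$sy[rows],
                                        exposureLabel = hset@exposureLabel,
                                        outcomeLabel = hset@outcomeLabel)
  theta_all <- mrIVW(hset)@beta
  corrected <- mrIVW(sub(keep))
  d_obs <- (theta_all - corrected@beta) / abs(corrected@beta)
  k <- length(intersect(outliers, p$snp_id))
  d_boot <- .with_seed(.child_seed(cfg$seed, 7L), function() {
    vapply(seq_len(cfg$nbSim), function(b) {
      drop_idx <- sample.int(nrow(p), k)
      theta_sub <- mrIVW(sub(-drop_idx))@beta
      (theta_all - theta_sub) / abs(theta_sub)
    }, numeric(1))
  })
  list(distortion = d_obs,
       pval = (1 + sum(abs(d_boot) >= abs(d_obs))) / (cfg$nbSim + 1),
       corrected = corrected)
}

#' Full MR-PRESSO analysis
#'
#' Runs the global, outlier and (when outliers are found) distortion tests
#' in one pass over a single simulated null, and returns a complete
#' [PressoResult-class]. Seeded: identical input and seed give identical
#' results.
#'
#' @inheritParams pressoGlobal
#' @return a [PressoResult-class].
#' @export
mrPresso <- function(hset, cfg = pressoConfig()) {
  core <- .presso_core(hset, cfg)
  rss_sim <- colSums(core$sims)
  global_p <- (1 + sum(rss_sim >= core$rss_obs)) / (cfg$nbSim + 1)
  praw <- (1 + rowSums(core$sims >= core$obs_j)) / (cfg$nbSim + 1)
  padj <- stats::setNames(pmin(1, praw * core$J), core$pairs$snp_id)
  outliers <- names(padj)[padj < cfg$sigThreshold]
  distortion_p <- NA_real_
  corrected <- NULL
  if (length(outliers) > 0 && sum(!(core$pairs$snp_id %in% outliers)) >= 2L) {
    dist <- pressoDistortion(hset, outliers, cfg)
    distortion_p <- dist$pval
    corrected <- dist$corrected
  }
  methods::new("PressoResult", rssObs = core$rss_obs, globalPval = global_p,
               outlierPvals = padj, outliers = outliers,
               distortionPval = distortion_p, corrected = corrected,
               nbSim = cfg$nbSim,
               seed = as.numeric(if (is.null(cfg$seed)) NA else cfg$seed))
}

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO (%d simulations): RSS = %.4g, global p = %.4g\n",
              object@nbSim, object@rssObs, object@globalPval))
  if (length(object@outlierPvals))
    cat("  outliers flagged:",
        if (length(object@outliers)) paste(object@outliers, collapse = ", ")
        else "none", "\n")
  if (!is.na(object@distortionPval))
    cat(sprintf("  distortion p = %.4g; corrected IVW beta = %.4g\n",
                object@distortionPval, object@corrected@beta))
})
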