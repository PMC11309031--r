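## The causal-effect estimator suite: Wald ratio, multiplicative
## random-effects IVW, MR-Egger, weighted median, and the mode-based
## estimators, plus BH-FDR adjustment.

#' Estimator settings
#'
#' @param bootstrapB parametric-bootstrap resamples used for the weighted-
#'   median and mode standard errors (minimum 100).
#' @param seed RNG seed driving all bootstrap draws (NULL leaves the RNG
#'   stream untouched).
#' @param phi bandwidth multiplier for the mode-based estimators.
#' @param alpha complement of the confidence level (0.05 gives 95% CIs).
#' @return a list of class `methodConfig`.
#' @export
methodConfig <- function(bootstrapB = 1000, seed = 1L, phi = 1, alpha = 0.05) {
  stopifnot(bootstrapB >= 100, phi > 0, alpha > 0, alpha < 1)
  structure(list(bootstrapB = as.integer(bootstrapB), seed = seed,
                 phi = phi, alpha = alpha), class = "methodConfig")
}

## shared constructor for estimate objects
.mr_estimate <- function(method, beta, se, pval, nsnp, alpha = 0.05,
                         intercept = NA_real_, interceptSE = NA_real_,
                         interceptPval = NA_real_, scalePhi = NA_real_) {
  z <- stats::qnorm(1 - alpha / 2)
  methods::new("MREstimate", method = method, beta = beta, se = se,
               ciLow = beta - z * se, ciHigh = beta + z * se, pval = pval,
               nsnp = as.integer(nsnp), intercept = intercept,
               interceptSE = interceptSE, interceptPval = interceptPval,
               scalePhi = scalePhi)
}

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s estimate (%d SNPs): beta = %.4g (95%% CI %.4g to %.4g), se = %.4g, p = %.3g\n",
              object@method, object@nsnp, object@beta, object@ciLow,
              object@ciHigh, object@se, object@pval))
  if (!is.na(object@intercept))
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n", object@intercept,
                object@interceptSE, object@interceptPval))
  if (!is.na(object@scalePhi))
    cat(sprintf("  overdispersion phi = %.4g\n", object@scalePhi))
})

#' Coerce an MREstimate to a one-row data.frame
#'
#' @param x an [MREstimate-class].
#' @param ... ignored.
#' @return data.frame with method, nsnp, beta, se, CI bounds and p-value.
#' @export
setMethod("as.data.frame", "MREstimate", function(x, ...) {
  data.frame(method = x@method, nsnp = x@nsnp, beta = x@beta, se = x@se,
             ci_low = x@ciLow, ci_high = x@ciHigh, pval = x@pval,
             egger_intercept = x@intercept, egger_intercept_pval = x@interceptPval,
             stringsAsFactors = FALSE)
})

#' Per-SNP Wald ratio
#'
#' Outcome effect divided by exposure effect, with the first-order standard
#' error `sy / |bx|`. The per-SNP building block of the median- and
#' mode-based estimators.
#'
#' @param bx,sx exposure effect and its SE.
#' @param by,sy outcome effect and its SE.
#' @param snp_id optional identifiers.
#' @return data.frame with `snp_id`, `ratio`, `se_ratio`, `weight`
#'   (inverse-variance weight).
#' @examples
#' waldRatio(0.5, 0.05, 0.4, 0.1)  # ratio 0.8, se 0.2
#' @export
waldRatio <- function(bx, sx, by, sy, snp_id = NULL) {
  if (any(bx == 0))
    stop("degenerate instrument: exposure effect is exactly zero", call. = FALSE)
  ratio <- by / bx
  se_ratio <- sy / abs(bx)
  data.frame(snp_id = if (is.null(snp_id)) as.character(seq_along(ratio)) else snp_id,
             ratio = ratio, se_ratio = se_ratio, weight = 1 / se_ratio^2,
             stringsAsFactors = FALSE)
}

.ratios <- function(hset) {
  p <- harmonizedPairs(hset)
  waldRatio(p$bx, p$sx, p$by, p$sy, p$snp_id)
}

#' Multiplicative random-effects IVW estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/sy^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`, fixed-effect SE
#' `(sum(w bx^2))^(-1/2)`. The reported SE multiplies the fixed-effect SE by
#' `max(1, sqrt(phi))` with `phi = Q/(J-1)` the residual overdispersion
#' (recorded in `scalePhi`), so the interval is never narrower than the
#' fixed-effect one. With a single SNP this reduces exactly to the Wald
#' ratio. P-value is two-sided normal.
#'
#' @param hset a [HarmonizedSet-class].
#' @param alpha CI level complement (default 0.05).
#' @return an [MREstimate-class] with method `"IVW"` (or `"Wald ratio"`
#'   when J = 1).
#' @export
mrIVW <- function(hset, alpha = 0.05) {
  p <- harmonizedPairs(hset)
  J <- nrow(p)
  if (J < 1L) .stop_empty_instruments("no harmonized pairs for IVW")
  if (any(p$bx == 0))
    stop("degenerate instrument: exposure effect is exactly zero", call. = FALSE)
  w <- 1 / p$sy^2
  sxx <- sum(w * p$bx^2)
  beta <- sum(w * p$bx * p$by) / sxx
  se_fe <- 1 / sqrt(sxx)
  phi <- NA_real_
  infl <- 1
  if (J > 1L) {
    Q <- sum(w * (p$by - beta * p$bx)^2)
    phi <- Q / (J - 1)
    infl <- max(1, sqrt(phi))
  }
  se <- se_fe * infl
  .mr_estimate(if (J == 1L) "Wald ratio" else "IVW", beta, se,
               .z_pval(beta / se), J, alpha, scalePhi = phi)
}

## oriented Egger fit shared by mrEgger, eggerInterceptTest and ruckerQ:
## pairs are flipped so all exposure effects are positive (Egger is not
## invariant to allele coding), then outcome effects are regressed on
## exposure effects with an intercept, weights 1/sy^2
.egger_fit <- function(hset) {
  p <- harmonizedPairs(hset)
  J <- nrow(p)
  if (J < 3L) .stop_insufficient(3L, J, "MR-Egger")
  s <- ifelse(p$bx < 0, -1, 1)
  bx <- abs(p$bx); by <- s * p$by
  w <- 1 / p$sy^2
  X <- cbind(intercept = 1, slope = bx)
  XtWX <- crossprod(X, w * X)
  coef <- drop(solve(XtWX, crossprod(X, w * by)))
  res <- by - drop(X %*% coef)
  rss <- sum(w * res^2)
  sigma <- sqrt(rss / (J - 2))
  se_unscaled <- sqrt(diag(solve(XtWX)))
  se <- se_unscaled * max(1, sigma)
  list(coef = coef, se = se, sigma = sigma, rss = rss, df = J - 2L, J = J)
}

#' MR-Egger regression
#'
#' Weighted linear regression of (orientation-corrected) outcome effects on
#' exposure effects with an intercept. The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy. Standard errors are inflated by the residual
#' scale when it exceeds 1; p-values use the t distribution with J - 2
#' degrees of freedom.
#'
#' @inheritParams mrIVW
#' @return an [MREstimate-class] with method `"MR Egger"` carrying the
#'   intercept test in its `intercept*` slots.
#' @export
mrEgger <- function(hset, alpha = 0.05) {
  fit <- .egger_fit(hset)
  t_slope <- fit$coef["slope"] / fit$se["slope"]
  t_int <- fit$coef["intercept"] / fit$se["intercept"]
  p_t <- function(t) 2 * stats::pt(-abs(t), df = fit$df)
  est <- .mr_estimate("MR Egger", unname(fit$coef["slope"]),
                      unname(fit$se["slope"]), p_t(t_slope), fit$J, alpha,
                      intercept = unname(fit$coef["intercept"]),
                      interceptSE = unname(fit$se["intercept"]),
                      interceptPval = p_t(t_int))
  ## t-based CI to match the t-based p-value
  tq <- stats::qt(1 - alpha / 2, df = fit$df)
  est@ciLow <- est@beta - tq * est@se
  est@ciHigh <- est@beta + tq * est@se
  est
}

## interpolated weighted median of ratios r with (unnormalized) weights w
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  if (any(w > 0.5)) return(r[which.max(w)])
  cw <- cumsum(w) - w / 2
  if (0.5 <= cw[1]) return(r[1])
  J <- length(r)
  if (0.5 >= cw[J]) return(r[J])
  k <- max(which(cw < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - cw[k]) / (cw[k + 1] - cw[k])
}

## parametric bootstrap over (bx, by) for any ratio-based point estimator;
## returns the SD of the bootstrap estimates
.ratio_bootstrap_se <- function(p, point_fun, B, seed) {
  .with_seed(seed, function() {
    J <- nrow(p)
    ests <- vapply(seq_len(B), function(b) {
      bx <- stats::rnorm(J, p$bx, p$sx)
      by <- stats::rnorm(J, p$by, p$sy)
      bx[bx == 0] <- .Machine$double.eps  # guard; zero draws have measure zero
      point_fun(by / bx, (p$sy / abs(bx))^2)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted-median estimator
#'
#' The causal estimate is the inverse-variance-weighted median of the
#' per-SNP Wald ratios: ratios are sorted, weights normalized to sum one,
#' and the estimate taken where the cumulative weight (at ratio midpoints)
#' crosses 0.5, linearly interpolating between the bracketing ratios. It is
#' consistent when SNPs carrying at least half the weight are valid
#' instruments. The standard error comes from a seeded parametric bootstrap
#' (resampling `bx` and `by` from their estimated sampling distributions);
#' CI and p-value are normal.
#'
#' @param hset a [HarmonizedSet-class] with at least 3 pairs.
#' @param cfg a [methodConfig()].
#' @return an [MREstimate-class] with method `"Weighted median"`.
#' @export
mrWeightedMedian <- function(hset, cfg = methodConfig()) {
  rt <- .ratios(hset)
  J <- nrow(rt)
  if (J < 3L) .stop_insufficient(3L, J, "the weighted median")
  beta <- .weighted_median(rt$ratio, rt$weight)
  se <- .ratio_bootstrap_se(harmonizedPairs(hset),
                            function(r, v) .weighted_median(r, 1 / v),
                            cfg$bootstrapB, cfg$seed)
  .mr_estimate("Weighted median", beta, se, .z_pval(beta / se), J, cfg$alpha)
}

## kernel-density mode of ratios; weights already normalized or not (scaled
## internally); bandwidth 0.9 * min(sd, mad) * J^(-1/5) * phi, falling back
## to the sd when the mad degenerates to zero
.mode_point <- function(r, w, phi = 1) {
  if (max(r) - min(r) < 1e-12) return(r[1])
  w <- w / sum(w)
  s <- stats::sd(r)
  m <- stats::mad(r)  # already scaled by 1.4826
  h0 <- min(s, m)
  if (h0 <= 0) h0 <- s
  h <- phi * 0.9 * h0 * length(r)^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 2001L)
  dens <- colSums(w * stats::dnorm(outer(r, grid, "-") / h))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted)
#'
#' The causal estimate is the location of the maximum of a Gaussian-kernel
#' density over the per-SNP Wald ratios, located on a 2001-point grid
#' spanning the ratios plus three bandwidths. The weighted variant weights
#' each kernel by the normalized inverse ratio variance; the simple variant
#' weights equally. Consistent when the largest group of SNPs sharing a
#' causal estimate are valid (the ZEMPA assumption). Bootstrap SE as for
#' [mrWeightedMedian()].
#'
#' @inheritParams mrWeightedMedian
#' @param weighted use inverse-variance kernel weights (TRUE) or equal
#'   weights (FALSE).
#' @return an [MREstimate-class] with method `"Weighted mode"` or
#'   `"Simple mode"`.
#' @export
mrMode <- function(hset, weighted = TRUE, cfg = methodConfig()) {
  rt <- .ratios(hset)
  J <- nrow(rt)
  if (J < 3L) .stop_insufficient(3L, J, "the mode-based estimator")
  wfun <- if (weighted) function(v) 1 / v else function(v) rep(1, length(v))
  beta <- .mode_point(rt$ratio, wfun(rt$se_ratio^2), cfg$phi)
  se <- .ratio_bootstrap_se(harmonizedPairs(hset),
                            function(r, v) .mode_point(r, wfun(v), cfg$phi),
                            cfg$bootstrapB, cfg$seed)
  .mr_estimate(if (weighted) "Weighted mode" else "Simple mode", beta, se,
               .z_pval(beta / se), J, cfg$alpha)
}

#' Run the five-estimator suite
#'
#' Computes MR-Egger, weighted median, IVW, simple mode and weighted mode
#' (in that order) on one harmonized set. With only 1 or 2 pairs the suite
#' downgrades to the Wald ratio / IVW alone, with the downgrade recorded in
#' `attr(, "downgrade")`. Bootstrap seeds for the median and modes are
#' derived deterministically from `cfg$seed`, so an identical set and seed
#' give bit-identical output.
#'
#' @inheritParams mrWeightedMedian
#' @return named list of [MREstimate-class] objects.
#' @export
runMethodSuite <- function(hset, cfg = methodConfig()) {
  J <- nPairs(hset)
  if (J >= 3L) {
    cfg_wm <- cfg; cfg_wm$seed <- .child_seed(cfg$seed, 1L)
    cfg_sm <- cfg; cfg_sm$seed <- .child_seed(cfg$seed, 2L)
    cfg_mo <- cfg; cfg_mo$seed <- .child_seed(cfg$seed, 3L)
    res <- list(mrEgger(hset, cfg$alpha),
                mrWeightedMedian(hset, cfg_wm),
                mrIVW(hset, cfg$alpha),
                mrMode(hset, weighted = FALSE, cfg_sm),
                mrMode(hset, weighted = TRUE, cfg_mo))
  } else {
    res <- list(mrIVW(hset, cfg$alpha))
    attr(res, "downgrade") <- sprintf(
      "only %d instrument(s): suite downgraded to %s", J,
      if (J == 1L) "the Wald ratio" else "IVW")
    message(attr(res, "downgrade"))
  }
  names(res) <- vapply(res, function(e) e@method, character(1))
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: `adj_i = min over ranks j >= rank(i) of
#' p_(j) * m / j`, capped at 1, returned in the original order. Delegates
#' to [stats::p.adjust()].
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values, elementwise at least as large as the input.
#' @examples
#' adjustFDR(c(0.022, 0.056, 0.008, 0.005))
#' @export
adjustFDR <- function(p) {
  if (length(p) == 0L) return(numeric())
  stopifnot(all(p > 0), all(p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Results table for a list of estimates
#'
#' Long-format data.frame mirroring the conventional MR results layout:
#' exposure, outcome, nsnp, method, beta, CI bounds, p-value.
#'
#' @param estimates list of [MREstimate-class] objects.
#' @param exposure,outcome trait labels.
#' @return data.frame, one row per method.
#' @export
mrTable <- function(estimates, exposure = "exposure", outcome = "outcome") {
  rows <- do.call(rbind, lapply(estimates, as.data.frame))
  cbind(data.frame(exposure = exposure, outcome = outcome,
                   stringsAsFactors = FALSE), rows, row.names = NULL)
}
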