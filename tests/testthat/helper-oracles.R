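# Independent oracles: deliberately different routes from the package
# implementation, used to freeze/check derived expected values.

# weighted least squares through the origin via stats::lm, with the
# multiplicative residual-scale inflation applied to the fixed-effect SE
oracle_wls_origin <- function(bx, by, sy) {
  w <- 1 / sy^2
  fit <- stats::lm(by ~ 0 + bx, weights = w)
  sm <- summary(fit)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  list(beta = unname(stats::coef(fit)[1]),
       se = se_fixed * max(1, sm$sigma),
       phi = sm$sigma^2)
}

# weighted linear regression with intercept via stats::lm (Egger oracle);
# SEs rebuilt from the unscaled covariance with the max(1, sigma) floor
oracle_wls_intercept <- function(bx, by, sy) {
  w <- 1 / sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  se_unscaled <- sm$coefficients[, "Std. Error"] / sm$sigma
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       se = unname(se_unscaled * max(1, sm$sigma)),
       sigma = sm$sigma)
}

# interpolated weighted median through stats::approx on midpoint
# cumulative weights
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  if (any(w > 0.5)) return(r[which.max(w)])
  cw <- cumsum(w) - w / 2
  stats::approx(cw, r, xout = 0.5, rule = 2)$y
}

# step-by-step greedy clumping simulation over explicit data.frame pools
oracle_clump <- function(v, ld_df, r2_thr, window_kb) {
  r2_of <- function(a, b) {
    if (a == b) return(1)
    hit <- (ld_df$snp_a == a & ld_df$snp_b == b) |
      (ld_df$snp_a == b & ld_df$snp_b == a)
    if (any(hit)) ld_df$r2[hit][1] else 0
  }
  kept <- character()
  pool <- v
  while (nrow(pool) > 0) {
    pool <- pool[order(pool$pval, pool$pos_bp, pool$snp_id), , drop = FALSE]
    top <- pool[1, ]
    kept <- c(kept, top$snp_id)
    drop <- vapply(seq_len(nrow(pool)), function(i) {
      pool$chrom[i] == top$chrom &&
        abs(pool$pos_bp[i] - top$pos_bp) <= window_kb * 1000 &&
        r2_of(top$snp_id, pool$snp_id[i]) >= r2_thr
    }, logical(1))
    drop[1] <- TRUE
    pool <- pool[!drop, , drop = FALSE]
  }
  v$snp_id[v$snp_id %in% kept]
}

# manual Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
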