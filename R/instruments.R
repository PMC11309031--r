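## Instrument selection: p-value thresholding, greedy LD clumping, and
## instrument-strength filtering (per-SNP variance explained and F).

#' Instrument-selection settings
#'
#' Defaults follow common MR practice: genome-wide significance 5e-8
#' (relaxed thresholds such as 5e-7 or 5e-6 can be supplied per exposure
#' when too few SNPs survive), LD pruning at r-squared < 0.001 within a
#' 10,000 kb window, and a minimum per-SNP F of 10.
#'
#' @param pThreshold significance cutoff (strict `<`).
#' @param clumpR2 LD r-squared threshold at or above which SNPs are clumped.
#' @param clumpWindowKb clumping window in kilobases.
#' @param fMin minimum per-SNP F-statistic.
#' @return a validated list of class `selectionConfig`.
#' @export
selectionConfig <- function(pThreshold = 5e-8, clumpR2 = 0.001,
                            clumpWindowKb = 10000, fMin = 10) {
  stopifnot(pThreshold > 0, pThreshold < 1, clumpR2 >= 0, clumpR2 <= 1,
            clumpWindowKb > 0, fMin >= 0)
  structure(list(pThreshold = pThreshold, clumpR2 = clumpR2,
                 clumpWindowKb = clumpWindowKb, fMin = fMin),
            class = "selectionConfig")
}

#' Construct / read a pairwise LD table
#'
#' @param table data.frame with columns `snp_a`, `snp_b`, `r2`. Symmetry is
#'   implied: each pair may be stored once in either order. Pairs absent
#'   from the table are treated as unlinked (r-squared 0).
#' @return an [LDTable-class].
#' @export
ldTable <- function(table) {
  table <- as.data.frame(table)
  table$snp_a <- as.character(table$snp_a)
  table$snp_b <- as.character(table$snp_b)
  table$r2 <- as.numeric(table$r2)
  methods::new("LDTable", table = table)
}

#' @describeIn ldTable read a 3-column TSV (`snp_a`, `snp_b`, `r2`).
#' @param path file to read.
#' @export
readLDTable <- function(path) {
  ldTable(utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
}

## r2 between one SNP and a vector of SNPs; absent pairs are 0, identical
## ids are 1
.ld_r2 <- function(ld, a, b) {
  out <- numeric(length(b))
  out[b == a] <- 1
  if (is.null(ld) || length(b) == 0L) return(out)
  tb <- ld@table
  key <- c(paste(tb$snp_a, tb$snp_b), paste(tb$snp_b, tb$snp_a))
  r2 <- c(tb$r2, tb$r2)
  hit <- match(paste(a, b), key)
  out[!is.na(hit)] <- r2[hit[!is.na(hit)]]
  out
}

#' Select instruments by p-value threshold
#'
#' Retains exactly the rows with `pval` strictly below `threshold`.
#'
#' @param x a [SummaryStats-class].
#' @param threshold significance cutoff.
#' @return a [SummaryStats-class] with the surviving rows; zero survivors is
#'   an error naming the threshold.
#' @export
selectByPvalue <- function(x, threshold = 5e-8) {
  stopifnot(methods::is(x, "SummaryStats"), threshold > 0, threshold <= 1)
  v <- variants(x)
  keep <- v$pval < threshold
  if (!any(keep))
    .stop_empty_instruments(sprintf("no SNP in '%s' has p < %g",
                                    traitLabel(x), threshold))
  summaryStats(v[keep, , drop = FALSE], traitLabel(x), sampleSize(x))
}

#' Greedy LD clumping
#'
#' Iteratively keeps the remaining SNP with the lowest p-value (ties broken
#' by genomic position, then identifier) and removes every remaining SNP on
#' the same chromosome within `clumpWindowKb` whose r-squared with it is at
#' or above `clumpR2`. The retained set is returned in the original row
#' order and is an independent set: no retained pair is both within the
#' window and at or above the LD threshold.
#'
#' @param x a [SummaryStats-class]; `chrom` and `pos_bp` must be present.
#' @param ld an [LDTable-class] or `NULL` (all pairs unlinked, so clumping
#'   reduces to distance-window pruning of perfectly-typed duplicates only
#'   when `clumpR2 > 0`; with `clumpR2 = 0` the window alone prunes).
#' @param config a [selectionConfig()].
#' @return a clumped [SummaryStats-class].
#' @export
greedyClump <- function(x, ld = NULL, config = selectionConfig()) {
  stopifnot(methods::is(x, "SummaryStats"))
  if (!is.null(ld)) stopifnot(methods::is(ld, "LDTable"))
  v <- variants(x)
  if (any(is.na(v$chrom)) || any(is.na(v$pos_bp)))
    stop("greedyClump needs chrom and pos_bp on every row for window pruning",
         call. = FALSE)
  n <- nrow(v)
  remaining <- rep(TRUE, n)
  keep <- logical(n)
  ord <- order(v$pval, v$pos_bp, v$snp_id)
  window_bp <- config$clumpWindowKb * 1000
  for (i in ord) {
    if (!remaining[i]) next
    keep[i] <- TRUE
    remaining[i] <- FALSE
    cand <- which(remaining & v$chrom == v$chrom[i] &
                    abs(v$pos_bp - v$pos_bp[i]) <= window_bp)
    if (length(cand)) {
      r2 <- .ld_r2(ld, v$snp_id[i], v$snp_id[cand])
      remaining[cand[r2 >= config$clumpR2]] <- FALSE
    }
  }
  summaryStats(v[keep, , drop = FALSE], traitLabel(x), sampleSize(x))
}

#' Per-SNP variance explained
#'
#' R-squared contributed by one SNP: `2 * beta^2 * EAF * (1 - EAF)`.
#' Symmetric in `EAF -> 1 - EAF` and maximal at EAF 0.5 for fixed beta.
#'
#' @param beta per-allele effect estimate (vectorized).
#' @param eaf effect-allele frequency (vectorized).
#' @param snp_id optional identifiers used in the missing-frequency error.
#' @return numeric vector of per-SNP R-squared.
#' @examples
#' varianceExplained(0.1, 0.5)   # 0.005
#' varianceExplained(0.2, 0.25)  # 0.015
#' @export
varianceExplained <- function(beta, eaf, snp_id = NULL) {
  if (any(is.na(eaf))) {
    who <- if (is.null(snp_id)) which(is.na(eaf)) else snp_id[is.na(eaf)]
    stop("effect-allele frequency missing for SNP(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(eaf >= 0), all(eaf <= 1))
  2 * beta^2 * eaf * (1 - eaf)
}

#' Instrument-strength F-statistic
#'
#' `F = (N - K - 1) / K * R2 / (1 - R2)` for K SNPs jointly explaining a
#' proportion `r2` of the variance of a trait measured in `n` individuals.
#' Strictly increasing in both `r2` and `n`.
#'
#' @param r2 variance explained, in `[0, 1)`.
#' @param n sample size; must exceed `k + 1`.
#' @param k number of SNPs (1 for a per-SNP F).
#' @return the F-statistic.
#' @examples
#' fStatistic(0.01, 1002, 1)  # 10.101...
#' @export
fStatistic <- function(r2, n, k = 1) {
  stopifnot(all(r2 >= 0), all(r2 < 1), all(k >= 1))
  if (any(n <= k + 1))
    stop("sample size must exceed k + 1 to compute an F-statistic", call. = FALSE)
  (n - k - 1) / k * r2 / (1 - r2)
}

#' Instrument strength summary
#'
#' Computes per-SNP variance explained and F (K = 1 per SNP) along with the
#' joint R-squared (sum over SNPs) and the joint F over all K SNPs.
#'
#' @param x a [SummaryStats-class] with `eaf` and a usable sample size
#'   (per-row `n` or the table-level `sampleSize`).
#' @return list with `r2PerSnp`, `fPerSnp` (named by snp_id), `r2Total`,
#'   `K`, `N`, `fJoint`.
#' @export
instrumentStrength <- function(x) {
  stopifnot(methods::is(x, "SummaryStats"))
  v <- variants(x)
  n_row <- ifelse(is.na(v$n), sampleSize(x), v$n)
  if (any(is.na(n_row)))
    stop("sample size unavailable for SNP(s): ",
         paste(v$snp_id[is.na(n_row)], collapse = ", "), call. = FALSE)
  r2j <- varianceExplained(v$beta, v$eaf, v$snp_id)
  fj <- fStatistic(r2j, n_row, k = 1)
  r2tot <- sum(r2j)
  N <- if (!is.na(sampleSize(x))) sampleSize(x) else stats::median(n_row)
  list(r2PerSnp = stats::setNames(r2j, v$snp_id),
       fPerSnp = stats::setNames(fj, v$snp_id),
       r2Total = r2tot, K = nrow(v), N = N,
       fJoint = fStatistic(min(r2tot, 1 - 1e-12), N, k = nrow(v)))
}

#' Drop weak instruments
#'
#' Retains SNPs whose per-SNP F-statistic (K = 1, that SNP's variance
#' explained) is at least `fMin`; SNPs with F strictly below the cutoff are
#' excluded and reported via `attr(, "dropped")`.
#'
#' @param x a [SummaryStats-class].
#' @param fMin minimum F (default 10).
#' @return filtered [SummaryStats-class]; dropping every SNP is an error.
#' @export
filterWeak <- function(x, fMin = 10) {
  strength <- instrumentStrength(x)
  keep <- strength$fPerSnp >= fMin
  v <- variants(x)
  if (!any(keep))
    .stop_empty_instruments(sprintf(
      "all %d SNPs in '%s' have per-SNP F < %g", nrow(v), traitLabel(x), fMin))
  out <- summaryStats(v[keep, , drop = FALSE], traitLabel(x), sampleSize(x))
  attr(out, "dropped") <- v$snp_id[!keep]
  out
}
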