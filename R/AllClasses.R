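## Central S4 containers. Validity lives here; constructors and accessors sit
## with their modules.

.NUCS <- c("A", "C", "G", "T")

## canonical column set for a summary-statistics table; optional columns are
## carried as NA so every SummaryStats has the same shape
.SUMMARY_COLS <- c("snp_id", "chrom", "pos_bp", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")
.MANDATORY_ROLES <- c("snp_id", "effect_allele", "other_allele", "beta", "se", "pval")

.HARMONIZED_COLS <- c("snp_id", "bx", "sx", "by", "sy", "eaf_x", "eaf_y", "action")
.RETAINED_ACTIONS <- c("kept", "flipped")
.DROP_ACTIONS <- c("dropped_palindromic", "dropped_mismatch", "dropped_absent")

#' GWAS summary statistics for one trait
#'
#' One row per variant with the association record needed by two-sample MR:
#' identifier, alleles, effect-allele frequency, effect size, standard error,
#' p-value and sample size. Optional fields (`chrom`, `pos_bp`, `eaf`, `n`)
#' are `NA` when unavailable.
#'
#' @slot traitLabel single character, the trait the table describes.
#' @slot variants data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @slot sampleSize table-level default sample size (`NA` if unknown).
#' @seealso [summaryStats()], [readSummaryStats()]
#' @export
setClass("SummaryStats",
         slots = c(traitLabel = "character",
                   variants = "data.frame",
                   sampleSize = "numeric"))

setValidity("SummaryStats", function(object) {
  msgs <- character()
  if (length(object@traitLabel) != 1L || is.na(object@traitLabel))
    msgs <- c(msgs, "traitLabel must be a single non-NA string")
  if (length(object@sampleSize) != 1L)
    msgs <- c(msgs, "sampleSize must be length 1 (NA allowed)")
  msgs <- c(msgs, .validate_variants(object@variants))
  if (length(msgs)) msgs else TRUE
})

#' Pairwise linkage-disequilibrium table
#'
#' Sparse symmetric r-squared lookup used by [greedyClump()]. Pairs absent
#' from the table are treated as unlinked (r-squared 0).
#'
#' @slot table data.frame with columns `snp_a`, `snp_b`, `r2`.
#' @seealso [ldTable()], [readLDTable()]
#' @export
setClass("LDTable", slots = c(table = "data.frame"))

setValidity("LDTable", function(object) {
  tb <- object@table
  msgs <- character()
  if (!all(c("snp_a", "snp_b", "r2") %in% names(tb)))
    msgs <- c(msgs, "LD table needs columns snp_a, snp_b, r2")
  else if (nrow(tb) && (any(!is.finite(tb$r2)) || any(tb$r2 < 0) || any(tb$r2 > 1)))
    msgs <- c(msgs, "r2 values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Harmonized exposure/outcome effect pairs
#'
#' Exposure and outcome per-SNP effects expressed on a common effect allele
#' (the exposure's), after resolving strand flips and excluding ambiguous
#' palindromic SNPs and SNPs absent from the outcome table. The exclusion log
#' accounts for every exposure SNP that was not retained.
#'
#' @slot exposureLabel,outcomeLabel trait labels.
#' @slot pairs data.frame with columns `snp_id`, `bx`, `sx`, `by`, `sy`,
#'   `eaf_x`, `eaf_y`, `action` (`"kept"` or `"flipped"`).
#' @slot exclusionLog data.frame (`snp_id`, `action`, `reason`) of dropped SNPs.
#' @seealso [harmonizeTables()]
#' @export
setClass("HarmonizedSet",
         slots = c(exposureLabel = "character",
                   outcomeLabel = "character",
                   pairs = "data.frame",
                   exclusionLog = "data.frame"))

setValidity("HarmonizedSet", function(object) {
  p <- object@pairs
  msgs <- character()
  if (!all(.HARMONIZED_COLS %in% names(p)))
    msgs <- c(msgs, paste("pairs must have columns:",
                          paste(.HARMONIZED_COLS, collapse = ", ")))
  else {
    if (nrow(p) == 0L)
      msgs <- c(msgs, "no harmonized pairs retained")
    if (anyDuplicated(p$snp_id))
      msgs <- c(msgs, "duplicated snp_id among harmonized pairs")
    if (nrow(p) && (any(!is.finite(p$sx)) || any(p$sx <= 0) ||
                    any(!is.finite(p$sy)) || any(p$sy <= 0)))
      msgs <- c(msgs, "retained pairs need finite positive sx and sy")
    if (nrow(p) && !all(p$action %in% .RETAINED_ACTIONS))
      msgs <- c(msgs, "retained actions must be 'kept' or 'flipped'")
  }
  if (length(msgs)) msgs else TRUE
})

#' A single causal-effect estimate
#'
#' Result container shared by all MR estimators: point estimate, standard
#' error, 95% confidence bounds, p-value and the number of instruments.
#' MR-Egger additionally carries its intercept (average directional
#' pleiotropy); IVW carries the multiplicative overdispersion scale `phi`.
#'
#' @slot method one of `"MR Egger"`, `"Weighted median"`, `"IVW"`,
#'   `"Simple mode"`, `"Weighted mode"`, `"Wald ratio"`.
#' @slot beta,se,ciLow,ciHigh,pval the estimate and its uncertainty.
#' @slot nsnp number of instruments used.
#' @slot intercept,interceptSE,interceptPval Egger intercept test (NA otherwise).
#' @slot scalePhi multiplicative overdispersion Q/(J-1) (IVW only, NA otherwise).
#' @export
setClass("MREstimate",
         slots = c(method = "character", beta = "numeric", se = "numeric",
                   ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                   nsnp = "integer", intercept = "numeric",
                   interceptSE = "numeric", interceptPval = "numeric",
                   scalePhi = "numeric"),
         prototype = prototype(intercept = NA_real_, interceptSE = NA_real_,
                               interceptPval = NA_real_, scalePhi = NA_real_))

setValidity("MREstimate", function(object) {
  msgs <- character()
  if (!is.finite(object@se) || object@se <= 0)
    msgs <- c(msgs, "se must be finite and > 0")
  if (!is.finite(object@pval) || object@pval <= 0 || object@pval > 1)
    msgs <- c(msgs, "pval must lie in (0, 1]")
  if (is.finite(object@beta) &&
      !(object@ciLow <= object@beta && object@beta <= object@ciHigh))
    msgs <- c(msgs, "confidence bounds must bracket beta")
  if (object@nsnp < 1L) msgs <- c(msgs, "nsnp must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Heterogeneity test result (Cochran's / Rucker's Q)
#'
#' @slot framework `"IVW"` (Cochran's Q, J-1 df) or `"Egger"` (Rucker's Q',
#'   J-2 df).
#' @slot Q,df,pval the statistic, its degrees of freedom and the upper
#'   chi-square tail probability.
#' @export
setClass("HeterogeneityResult",
         slots = c(framework = "character", Q = "numeric", df = "integer",
                   pval = "numeric"))

#' Egger-intercept pleiotropy test result
#'
#' @slot intercept,interceptSE the estimated average directional pleiotropy
#'   and its standard error.
#' @slot pval two-sided t-test p-value (J-2 df).
#' @slot df residual degrees of freedom.
#' @export
setClass("PleiotropyResult",
         slots = c(intercept = "numeric", interceptSE = "numeric",
                   pval = "numeric", df = "integer"))

#' MR-PRESSO result
#'
#' Global pleiotropy test (simulation-based residual sum of squares),
#' per-SNP outlier test (Bonferroni-adjusted) and, when outliers are found,
#' the distortion test with the outlier-corrected IVW estimate.
#'
#' @slot rssObs observed residual sum of squares.
#' @slot globalPval Monte-Carlo p-value (add-one convention; never below
#'   1/(nbSim + 1)).
#' @slot outlierPvals named per-SNP Bonferroni-adjusted p-values.
#' @slot outliers snp_ids flagged at the significance threshold.
#' @slot distortionPval distortion-test p-value (NA when no outliers).
#' @slot corrected outlier-corrected [MREstimate-class] or `NULL`.
#' @slot nbSim,seed simulation settings used.
#' @export
setClass("PressoResult",
         slots = c(rssObs = "numeric", globalPval = "numeric",
                   outlierPvals = "numeric", outliers = "character",
                   distortionPval = "numeric", corrected = "ANY",
                   nbSim = "integer", seed = "numeric"),
         prototype = prototype(distortionPval = NA_real_, corrected = NULL))

#' Two-step MR mediation result
#'
#' Indirect effect (beta1 x beta2), proportion mediated (beta1 x beta2 /
#' beta3) and parametric-bootstrap standard errors and 95% percentile
#' intervals for one exposure -> mediator -> outcome pathway.
#'
#' @slot labels exposure, mediator, outcome labels.
#' @slot inputs named numeric (beta1, se1, beta2, se2, beta3, se3).
#' @slot indirect,proportion point estimates.
#' @slot seIndirect,seProportion bootstrap standard deviations.
#' @slot ciIndirect,ciProportion 2.5/97.5 bootstrap percentiles.
#' @slot pval two-sided normal p from indirect/seIndirect.
#' @slot B,seed bootstrap settings used.
#' @slot unstable TRUE when >1% of bootstrap draws had |beta3*| ~ 0, making
#'   the proportion numerically unstable.
#' @export
setClass("MediationResult",
         slots = c(labels = "character", inputs = "numeric",
                   indirect = "numeric", proportion = "numeric",
                   seIndirect = "numeric", seProportion = "numeric",
                   ciIndirect = "numeric", ciProportion = "numeric",
                   pval = "numeric", B = "integer", seed = "numeric",
                   unstable = "logical"))

#' A simulated three-trait GWAS study
#'
#' Exposure, mediator and outcome summary tables over a shared variant panel,
#' plus the generating truth (per-SNP effects, pleiotropy, structural
#' parameters) sufficient to score any estimator.
#'
#' @slot exposure,mediator,outcome [SummaryStats-class] tables.
#' @slot truth list of generating parameters (see [simulateStudy()]).
#' @export
setClass("SimulatedStudy",
         slots = c(exposure = "SummaryStats", mediator = "SummaryStats",
                   outcome = "SummaryStats", truth = "list"))

#' Pipeline results report
#'
#' @slot univariable long-format estimates (one row per exposure x method).
#' @slot sensitivity one row per exposure (Q tests, Egger intercept, PRESSO).
#' @slot mediation one row per exposure -> mediator -> outcome pathway.
#' @slot failures contained per-exposure/pathway failures with reasons.
#' @slot meta run metadata (seed, config, package version).
#' @export
setClass("ResultsReport",
         slots = c(univariable = "data.frame", sensitivity = "data.frame",
                   mediation = "data.frame", failures = "data.frame",
                   meta = "list"))
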