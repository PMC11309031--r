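## Allele harmonization: put exposure and outcome effects on a shared
## effect allele, resolving label swaps and strand flips, and drop what
## cannot be resolved.

#' Is an allele pair palindromic?
#'
#' A palindromic (ambiguous-strand) SNP has alleles that are reverse
#' complements of each other (A/T or C/G), so strand cannot be resolved from
#' allele labels alone.
#'
#' @param a1,a2 single-letter alleles (vectorized).
#' @return logical vector.
#' @examples
#' isPalindromic("A", "T")  # TRUE
#' isPalindromic("A", "G")  # FALSE
#' @export
isPalindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  stopifnot(all(a1 %in% .NUCS), all(a2 %in% .NUCS))
  a2 == .revcomp(a1)
}

#' Align one outcome record to an exposure record
#'
#' Re-expresses the outcome association on the exposure's effect allele.
#' Same-order alleles are kept; swapped alleles are flipped (`by` negated,
#' `eaf_y` complemented); non-palindromic alleles are additionally compared
#' up to reverse complement (strand correction) before being declared a
#' mismatch. Palindromic SNPs are resolved by allele frequency: if either
#' table's frequency lies inside `ambiguityBand` (or is missing) the SNP is
#' dropped as ambiguous, otherwise minor/major status decides orientation.
#'
#' @param exposure,outcome single-record lists or one-row data.frames with
#'   fields `snp_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`.
#' @param ambiguityBand frequency interval within which a palindromic SNP is
#'   considered unresolvable (default `c(0.3, 0.7)`).
#' @return list with `action` (one of `kept`, `flipped`,
#'   `dropped_palindromic`, `dropped_mismatch`) and, for retained SNPs, the
#'   transformed `by` and `eaf_y`.
#' @export
alignRecord <- function(exposure, outcome, ambiguityBand = c(0.3, 0.7)) {
  if (exposure$snp_id != outcome$snp_id)
    stop("alignRecord called on different SNPs: ", exposure$snp_id, " vs ",
         outcome$snp_id, call. = FALSE)
  a1x <- toupper(exposure$effect_allele); a2x <- toupper(exposure$other_allele)
  a1y <- toupper(outcome$effect_allele);  a2y <- toupper(outcome$other_allele)
  by <- outcome$beta
  eaf_y <- if (is.null(outcome$eaf)) NA_real_ else outcome$eaf
  eaf_x <- if (is.null(exposure$eaf)) NA_real_ else exposure$eaf

  keep <- function() list(action = "kept", by = by, eaf_y = eaf_y)
  flip <- function() list(action = "flipped", by = -by,
                          eaf_y = if (is.na(eaf_y)) NA_real_ else 1 - eaf_y)
  drop <- function(action) list(action = action, by = NA_real_, eaf_y = NA_real_)

  if (isPalindromic(a1x, a2x)) {
    ## labels are uninformative (a strand flip permutes them); the allele
    ## sets must still agree
    if (!setequal(c(a1y, a2y), c(a1x, a2x))) return(drop("dropped_mismatch"))
    if (is.na(eaf_x) || is.na(eaf_y)) return(drop("dropped_palindromic"))
    inside <- function(f) f >= ambiguityBand[1] & f <= ambiguityBand[2]
    if (inside(eaf_x) || inside(eaf_y)) return(drop("dropped_palindromic"))
    ## frequencies decide orientation: same minor/major status means the
    ## outcome's labelled effect allele is the exposure's effect allele
    if ((eaf_x < 0.5) == (eaf_y < 0.5)) keep() else flip()
  } else {
    if (a1y == a1x && a2y == a2x) return(keep())
    if (a1y == a2x && a2y == a1x) return(flip())
    ## try the other strand
    c1y <- .revcomp(a1y); c2y <- .revcomp(a2y)
    if (c1y == a1x && c2y == a2x) return(keep())
    if (c1y == a2x && c2y == a1x) return(flip())
    drop("dropped_mismatch")
  }
}

#' Harmonize exposure and outcome summary tables
#'
#' Produces one harmonized pair per exposure SNP found in the outcome table
#' (no proxy substitution); exposure SNPs absent from the outcome are logged
#' as `dropped_absent`, palindromic SNPs with ambiguous frequencies as
#' `dropped_palindromic`, irreconcilable allele sets as `dropped_mismatch`.
#' Every exposure SNP is accounted for: the number of retained pairs plus
#' the number of exclusion-log rows equals the number of exposure SNPs.
#'
#' @param exposure,outcome [SummaryStats-class] tables.
#' @param ambiguityBand see [alignRecord()].
#' @return a [HarmonizedSet-class]; zero retained pairs is an error.
#' @export
harmonizeTables <- function(exposure, outcome, ambiguityBand = c(0.3, 0.7)) {
  ev <- variants(exposure); ov <- variants(outcome)
  idx <- match(ev$snp_id, ov$snp_id)
  n <- nrow(ev)
  action <- character(n); by <- numeric(n); eaf_y <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(idx[i])) {
      action[i] <- "dropped_absent"; by[i] <- NA_real_; eaf_y[i] <- NA_real_
    } else {
      res <- alignRecord(as.list(ev[i, ]), as.list(ov[idx[i], ]),
                         ambiguityBand = ambiguityBand)
      action[i] <- res$action; by[i] <- res$by; eaf_y[i] <- res$eaf_y
    }
  }
  retained <- action %in% .RETAINED_ACTIONS
  pairs <- data.frame(
    snp_id = ev$snp_id[retained],
    bx = ev$beta[retained], sx = ev$se[retained],
    by = by[retained], sy = ov$se[idx[retained]],
    eaf_x = ev$eaf[retained], eaf_y = eaf_y[retained],
    action = action[retained], stringsAsFactors = FALSE)
  excl <- data.frame(
    snp_id = ev$snp_id[!retained], action = action[!retained],
    reason = c(dropped_absent = "absent from outcome table",
               dropped_palindromic = "palindromic with ambiguous frequency",
               dropped_mismatch = "allele sets irreconcilable")[action[!retained]],
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL; rownames(excl) <- NULL
  if (nrow(pairs) == 0L)
    .stop_empty_instruments(sprintf(
      "no harmonizable SNPs between '%s' and '%s' (%d absent, %d palindromic, %d mismatched)",
      traitLabel(exposure), traitLabel(outcome),
      sum(action == "dropped_absent"), sum(action == "dropped_palindromic"),
      sum(action == "dropped_mismatch")))
  methods::new("HarmonizedSet", exposureLabel = traitLabel(exposure),
               outcomeLabel = traitLabel(outcome), pairs = pairs,
               exclusionLog = excl)
}

#' @describeIn harmonizeTables retained pairs accessor.
#' @param x a `HarmonizedSet`.
#' @export
setMethod("harmonizedPairs", "HarmonizedSet", function(x) x@pairs)

#' @describeIn harmonizeTables exclusion log accessor.
#' @export
setMethod("exclusionLog", "HarmonizedSet", function(x) x@exclusionLog)

#' @describeIn harmonizeTables number of retained pairs.
#' @export
setMethod("nPairs", "HarmonizedSet", function(x) nrow(x@pairs))

setMethod("show", "HarmonizedSet", function(object) {
  cat("HarmonizedSet:", object@exposureLabel, "->", object@outcomeLabel, "\n",
      " ", nrow(object@pairs), "retained pairs,",
      nrow(object@exclusionLog), "excluded\n")
  print(utils::head(object@pairs, 3L))
  if (nrow(object@pairs) > 3L) cat("  ...\n")
})

## build a HarmonizedSet directly from aligned vectors (internal, used by
## simulations and tests where alleles are known to match)
.harmonized_set <- function(snp_id, bx, sx, by, sy, eaf_x = NA_real_,
                            eaf_y = NA_real_, exposureLabel = "exposure",
                            outcomeLabel = "outcome") {
  n <- length(snp_id)
  methods::new("HarmonizedSet", exposureLabel = exposureLabel,
               outcomeLabel = outcomeLabel,
               pairs = data.frame(snp_id = snp_id, bx = bx, sx = sx, by = by,
                                  sy = sy, eaf_x = rep_len(eaf_x, n),
                                  eaf_y = rep_len(eaf_y, n),
                                  action = rep("kept", n),
                                  stringsAsFactors = FALSE),
               exclusionLog = data.frame(snp_id = character(), action = character(),
                                         reason = character(),
                                         stringsAsFactors = FALSE))
}

#' Write harmonized pairs and the exclusion log as TSV
#'
#' @param x a [HarmonizedSet-class].
#' @param path destination for the pairs table.
#' @param exclusionPath optional destination for the exclusion log.
#' @return invisibly, `path`.
#' @export
writeHarmonized <- function(x, path, exclusionPath = NULL) {
  stopifnot(methods::is(x, "HarmonizedSet"))
  utils::write.table(harmonizedPairs(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(exclusionPath))
    utils::write.table(exclusionLog(x), exclusionPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
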