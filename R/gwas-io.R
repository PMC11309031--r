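## Reading, validating and writing GWAS summary-statistic tables.

## row/table-level invariant checks on a canonical variants data.frame;
## returns a character vector of human-readable violations (empty when clean)
.validate_variants <- function(v) {
  msgs <- character()
  missing_cols <- setdiff(.SUMMARY_COLS, names(v))
  if (length(missing_cols))
    return(paste("missing canonical columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(v) == 0L) return("table has no records")
  if (anyDuplicated(v$snp_id)) {
    dup <- unique(v$snp_id[duplicated(v$snp_id)])
    msgs <- c(msgs, paste0("duplicate snp_id: ", paste(dup, collapse = ", ")))
  }
  msgs <- c(msgs, .row_violations(v))
  msgs
}

## per-row invariant violations, each naming the snp_id and the field
.row_violations <- function(v) {
  msgs <- character()
  flag <- function(bad, field, why) {
    if (any(bad)) paste0("snp ", v$snp_id[bad], ": ", field, " ", why) else character()
  }
  msgs <- c(msgs, flag(!is.finite(v$beta), "beta", "is not a finite number"))
  msgs <- c(msgs, flag(!is.finite(v$se) | v$se <= 0, "se", "must be > 0"))
  msgs <- c(msgs, flag(!is.finite(v$pval) | v$pval <= 0 | v$pval > 1,
                       "pval", "must lie in (0, 1]"))
  msgs <- c(msgs, flag(!is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1),
                       "eaf", "must lie in [0, 1]"))
  msgs <- c(msgs, flag(!(v$effect_allele %in% .NUCS), "effect_allele",
                       "must be one of A, C, G, T"))
  msgs <- c(msgs, flag(!(v$other_allele %in% .NUCS), "other_allele",
                       "must be one of A, C, G, T"))
  both_ok <- v$effect_allele %in% .NUCS & v$other_allele %in% .NUCS
  msgs <- c(msgs, flag(both_ok & v$effect_allele == v$other_allele,
                       "alleles", "effect and other allele must differ"))
  msgs <- c(msgs, flag(!is.na(v$n) & v$n <= 0, "n", "must be positive"))
  msgs
}

## coerce an arbitrary data.frame into canonical shape (does not validate)
.canonical_variants <- function(df) {
  out <- data.frame(
    snp_id = as.character(df$snp_id),
    chrom = if ("chrom" %in% names(df)) as.character(df$chrom) else NA_character_,
    pos_bp = if ("pos_bp" %in% names(df)) as.integer(df$pos_bp) else NA_integer_,
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele = toupper(as.character(df$other_allele)),
    eaf = if ("eaf" %in% names(df)) as.numeric(df$eaf) else NA_real_,
    beta = as.numeric(df$beta),
    se = as.numeric(df$se),
    pval = as.numeric(df$pval),
    n = if ("n" %in% names(df)) as.numeric(df$n) else NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Construct a summary-statistics table
#'
#' Builds a validated [SummaryStats-class] object from a data.frame holding
#' (at least) `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#' `pval`; `chrom`, `pos_bp`, `eaf` and `n` are optional and stored as `NA`
#' when absent. Alleles are upper-cased.
#'
#' @param variants data.frame of per-SNP records.
#' @param traitLabel trait name.
#' @param sampleSize table-level default sample size (optional).
#' @return a [SummaryStats-class] object.
#' @examples
#' summaryStats(data.frame(snp_id = "rs1", effect_allele = "a",
#'                         other_allele = "g", beta = 0.1, se = 0.02,
#'                         pval = 1e-9), "example trait")
#' @export
summaryStats <- function(variants, traitLabel, sampleSize = NA_real_) {
  missing_roles <- setdiff(.MANDATORY_ROLES, names(variants))
  if (length(missing_roles))
    stop("missing mandatory column(s): ", paste(missing_roles, collapse = ", "),
         call. = FALSE)
  v <- .canonical_variants(variants)
  methods::new("SummaryStats", traitLabel = as.character(traitLabel),
               variants = v, sampleSize = as.numeric(sampleSize))
}

#' @describeIn summaryStats trait label accessor.
#' @param x a `SummaryStats` object.
#' @export
setMethod("traitLabel", "SummaryStats", function(x) x@traitLabel)

#' @describeIn summaryStats variant table accessor (canonical data.frame).
#' @export
setMethod("variants", "SummaryStats", function(x) x@variants)

#' @describeIn summaryStats table-level sample size.
#' @export
setMethod("sampleSize", "SummaryStats", function(x) x@sampleSize)

#' @describeIn summaryStats number of variants.
#' @export
setMethod("nVariants", "SummaryStats", function(x) nrow(x@variants))

setMethod("show", "SummaryStats", function(object) {
  cat("SummaryStats:", object@traitLabel, "\n",
      " ", nrow(object@variants), "variants;",
      "sample size:", ifelse(is.na(object@sampleSize), "unspecified",
                             format(object@sampleSize)), "\n")
  print(utils::head(object@variants, 3L))
  if (nrow(object@variants) > 3L) cat("  ...\n")
})

#' Read a GWAS summary-statistics file
#'
#' Reads a headered delimited text file into a [SummaryStats-class] object,
#' mapping file column names onto the canonical roles via `columnMap`. Rows
#' violating record invariants (non-positive `se`, p-value outside (0, 1],
#' invalid alleles, ...) are dropped with a per-row report by default, or
#' rejected wholesale with `strict = TRUE`.
#'
#' @param path file to read.
#' @param traitLabel trait name for the table.
#' @param columnMap named character vector mapping roles to file column
#'   names, e.g. `c(beta = "BETA_HAT", se = "SE")`. Roles absent from the
#'   map are taken to have their canonical names in the header. Must cover
#'   `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`.
#' @param delim `"tab"` (default) or `"comma"`.
#' @param sampleSize table-level default sample size.
#' @param strict if TRUE, any invalid row is an error instead of a dropped
#'   row.
#' @return a [SummaryStats-class] object; dropped-row reports are attached
#'   as `attr(, "rejected")`.
#' @export
readSummaryStats <- function(path, traitLabel, columnMap = NULL,
                             delim = c("tab", "comma"),
                             sampleSize = NA_real_, strict = FALSE) {
  delim <- match.arg(delim)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE,
                           sep = if (delim == "tab") "\t" else ",",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  map <- stats::setNames(.SUMMARY_COLS, .SUMMARY_COLS)
  if (!is.null(columnMap)) {
    unknown <- setdiff(names(columnMap), .SUMMARY_COLS)
    if (length(unknown))
      stop("unknown column roles in columnMap: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    map[names(columnMap)] <- columnMap
  }
  missing_mand <- .MANDATORY_ROLES[!(map[.MANDATORY_ROLES] %in% names(raw))]
  if (length(missing_mand))
    stop("mandatory role(s) not found in file header: ",
         paste(sprintf("%s (column '%s')", missing_mand, map[missing_mand]),
               collapse = ", "), call. = FALSE)
  present <- map[map %in% names(raw)]
  df <- raw[, unname(present), drop = FALSE]
  names(df) <- names(present)

  ## numeric coercion with line-level reporting (header is line 1)
  for (col in intersect(c("pos_bp", "eaf", "beta", "se", "pval", "n"), names(df))) {
    coerced <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "" & is.na(coerced))
    if (length(bad)) {
      msg <- sprintf("line %d: column '%s' value '%s' is not numeric",
                     bad + 1L, present[[col]], df[[col]][bad])
      if (strict) stop(paste(msg, collapse = "; "), call. = FALSE)
      warning(paste(msg, collapse = "\n"), call. = FALSE)
    }
    df[[col]] <- coerced
  }

  v <- .canonical_variants(df)
  bad_rows <- .bad_row_index(v)
  reports <- .row_violations(v)
  if (length(bad_rows)) {
    if (strict)
      stop("invalid rows in ", path, ":\n", paste(reports, collapse = "\n"),
           call. = FALSE)
    message(length(bad_rows), " row(s) dropped while reading '", path, "':\n",
            paste(reports, collapse = "\n"))
    v <- v[-bad_rows, , drop = FALSE]
    rownames(v) <- NULL
  }
  if (nrow(v) == 0L) stop("no valid rows in ", path, call. = FALSE)
  out <- summaryStats(v, traitLabel = traitLabel, sampleSize = sampleSize)
  attr(out, "rejected") <- reports
  out
}

## indices of rows violating any record-level invariant
.bad_row_index <- function(v) {
  bad <- !is.finite(v$beta) | !is.finite(v$se) | v$se <= 0 |
    !is.finite(v$pval) | v$pval <= 0 | v$pval > 1 |
    (!is.na(v$eaf) & (v$eaf < 0 | v$eaf > 1)) |
    !(v$effect_allele %in% .NUCS) | !(v$other_allele %in% .NUCS) |
    (!is.na(v$n) & v$n <= 0)
  same <- v$effect_allele == v$other_allele &
    v$effect_allele %in% .NUCS
  which(bad | same)
}

#' Write a summary-statistics table to TSV
#'
#' Writes the canonical columns as a headered tab-separated file. Optional
#' columns that are entirely `NA` are omitted, so a read/write round trip
#' preserves absence. Writing an empty table is an error.
#'
#' @param x a [SummaryStats-class] object.
#' @param path destination file.
#' @return invisibly, `path`.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(methods::is(x, "SummaryStats"))
  v <- variants(x)
  if (nrow(v) == 0L) stop("refusing to write an empty summary table", call. = FALSE)
  optional <- c("chrom", "pos_bp", "eaf", "n")
  drop <- optional[vapply(v[optional], function(col) all(is.na(col)), logical(1))]
  v <- v[, setdiff(names(v), drop), drop = FALSE]
  utils::write.table(v, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a summary-statistics table
#'
#' Reports (never raises) all record- and table-level invariant violations:
#' non-positive standard errors, p-values outside (0, 1], allele problems,
#' frequencies outside [0, 1], duplicate identifiers. The report is
#' order-independent: permuting rows yields the same set of violations.
#'
#' @param x a [SummaryStats-class] object or a data.frame in canonical or
#'   near-canonical form.
#' @return character vector of violation descriptions (empty when clean).
#' @export
validateSummaryStats <- function(x) {
  v <- if (methods::is(x, "SummaryStats")) variants(x) else {
    missing_roles <- setdiff(.MANDATORY_ROLES, names(x))
    if (length(missing_roles))
      return(paste("missing mandatory column(s):",
                   paste(missing_roles, collapse = ", ")))
    .canonical_variants(x)
  }
  sort(.validate_variants(v))
}
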