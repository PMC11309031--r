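## Config-driven orchestration of the three-stage design: univariable MR
## per exposure, sensitivity battery, FDR across the configured family,
## and two-step mediation for exposures with significant total effects.

.default_config <- function() {
  list(seed = 1L, outdir = "mr-results", log_level = "info",
       ambiguity_band = c(0.3, 0.7),
       selection = list(p_threshold = 5e-8, clump_r2 = 0.001,
                        clump_window_kb = 10000, f_min = 10),
       method = list(bootstrap_B = 1000, phi = 1, alpha = 0.05),
       presso = list(nb_sim = 1000, sig_threshold = 0.05),
       mediation = list(B = 10000, screen_alpha = 0.05),
       fdr_family = "IVW",
       ld_table = NULL, exposures = list(), outcome = NULL, mediators = list())
}

## shallow-merge user values over defaults, recursing one level into the
## known sub-lists
.merge_config <- function(user) {
  cfg <- .default_config()
  for (key in names(user)) {
    if (key %in% c("selection", "method", "presso", "mediation") &&
        is.list(user[[key]])) {
      for (k2 in names(user[[key]])) cfg[[key]][[k2]] <- user[[key]][[k2]]
    } else cfg[[key]] <- user[[key]]
  }
  cfg
}

#' Build or read an analysis configuration
#'
#' The configuration names at least one exposure and one outcome summary
#' table, optionally mediators and an LD table, plus the selection,
#' estimator, PRESSO and mediation settings. When `file` is given it is
#' read as YAML and any `...` arguments override its keys.
#'
#' @param file optional YAML file.
#' @param ... configuration entries overriding the file/defaults, e.g.
#'   `exposures = list(list(label = "coffee", path = "exp.tsv",
#'   p_threshold = 5e-8))`, `outcome = list(label = "CAC", path =
#'   "out.tsv")`, `seed = 7`.
#' @return a validated list of class `analysisConfig`.
#' @export
analysisConfig <- function(file = NULL, ...) {
  user <- if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
    yaml::read_yaml(file)
  } else list()
  dots <- list(...)
  for (k in names(dots)) user[[k]] <- dots[[k]]
  cfg <- .merge_config(user)
  if (length(cfg$exposures) == 0L)
    stop("config must name at least one exposure", call. = FALSE)
  if (is.null(cfg$outcome))
    stop("config must name an outcome", call. = FALSE)
  sel <- cfg$selection
  selectionConfig(sel$p_threshold, sel$clump_r2, sel$clump_window_kb, sel$f_min)
  structure(cfg, class = "analysisConfig")
}

.log <- function(cfg, level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## instrument pipeline for one exposure spec: read -> p filter -> clump ->
## strength filter; returns the instrument table
.instruments_for <- function(spec, cfg, ld) {
  tab <- readSummaryStats(spec$path, spec$label,
                          columnMap = cfg$column_map,
                          sampleSize = spec$sample_size %||% NA_real_)
  thr <- spec$p_threshold %||% cfg$selection$p_threshold
  sel <- selectionConfig(thr, cfg$selection$clump_r2,
                         cfg$selection$clump_window_kb, cfg$selection$f_min)
  tab <- selectByPvalue(tab, sel$pThreshold)
  n_sig <- nVariants(tab)
  tab <- greedyClump(tab, ld, sel)
  n_clump <- nVariants(tab)
  tab <- filterWeak(tab, sel$fMin)
  .log(cfg, "info", spec$label, ": ", n_sig, " significant, ", n_clump,
       " after clumping, ", nVariants(tab), " after F filter")
  tab
}

.sensitivity_row <- function(label, outcome_label, hset, cfg) {
  J <- nPairs(hset)
  q_ivw <- if (J >= 2L) cochranQ(hset, "IVW") else NULL
  q_egg <- if (J >= 3L) cochranQ(hset, "Egger") else NULL
  plei <- if (J >= 3L) eggerInterceptTest(hset) else NULL
  presso <- if (J >= 4L)
    mrPresso(hset, pressoConfig(cfg$presso$nb_sim,
                                .child_seed(cfg$seed, 11L),
                                cfg$presso$sig_threshold)) else NULL
  data.frame(
    exposure = label, outcome = outcome_label, nsnp = J,
    Q = if (is.null(q_ivw)) NA_real_ else q_ivw@Q,
    Q_df = if (is.null(q_ivw)) NA_integer_ else q_ivw@df,
    Q_pval = if (is.null(q_ivw)) NA_real_ else q_ivw@pval,
    Q_egger = if (is.null(q_egg)) NA_real_ else q_egg@Q,
    Q_egger_pval = if (is.null(q_egg)) NA_real_ else q_egg@pval,
    egger_intercept = if (is.null(plei)) NA_real_ else plei@intercept,
    egger_intercept_pval = if (is.null(plei)) NA_real_ else plei@pval,
    presso_global_pval = if (is.null(presso)) NA_real_ else presso@globalPval,
    n_outliers = if (is.null(presso)) NA_integer_ else length(presso@outliers),
    distortion_pval = if (is.null(presso)) NA_real_ else presso@distortionPval,
    stringsAsFactors = FALSE)
}

#' Univariable MR across all configured exposures
#'
#' Per exposure: p-value selection, greedy LD clumping, F-statistic
#' filtering, harmonization against the outcome, the five-estimator suite,
#' and the sensitivity battery; then BH-FDR across the configured p-value
#' family (IVW p-values by default). Per-exposure failures (e.g. no
#' surviving instruments) are contained and recorded in the failure log
#' without aborting other exposures.
#'
#' @param cfg an [analysisConfig()].
#' @return a [ResultsReport-class] with the univariable and sensitivity
#'   tables filled.
#' @export
runUnivariable <- function(cfg) {
  stopifnot(inherits(cfg, "analysisConfig"))
  ld <- if (!is.null(cfg$ld_table)) readLDTable(cfg$ld_table) else NULL
  outcome <- readSummaryStats(cfg$outcome$path, cfg$outcome$label,
                              columnMap = cfg$column_map)
  univ <- list(); sens <- list(); failures <- list()
  for (spec in cfg$exposures) {
    res <- tryCatch({
      instruments <- .instruments_for(spec, cfg, ld)
      hset <- harmonizeTables(instruments, outcome, cfg$ambiguity_band)
      mcfg <- methodConfig(cfg$method$bootstrap_B,
                           .child_seed(cfg$seed, 5L),
                           cfg$method$phi, cfg$method$alpha)
      suite <- runMethodSuite(hset, mcfg)
      list(table = mrTable(suite, spec$label, cfg$outcome$label),
           sens = .sensitivity_row(spec$label, cfg$outcome$label, hset, cfg))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      .log(cfg, "warn", spec$label, " failed: ", conditionMessage(res))
      failures[[length(failures) + 1L]] <-
        data.frame(stage = "univariable", unit = spec$label,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      univ[[length(univ) + 1L]] <- res$table
      sens[[length(sens) + 1L]] <- res$sens
    }
  }
  univ_df <- if (length(univ)) do.call(rbind, univ) else
    data.frame(exposure = character(), outcome = character())
  ## FDR across the configured family (one p per exposure)
  if (nrow(univ_df)) {
    univ_df$pval_fdr <- NA_real_
    fam <- univ_df$method == cfg$fdr_family
    if (any(fam)) univ_df$pval_fdr[fam] <- adjustFDR(univ_df$pval[fam])
  }
  methods::new("ResultsReport",
               univariable = univ_df,
               sensitivity = if (length(sens)) do.call(rbind, sens) else
                 data.frame(),
               mediation = data.frame(),
               failures = if (length(failures)) do.call(rbind, failures) else
                 data.frame(stage = character(), unit = character(),
                            reason = character(), stringsAsFactors = FALSE),
               meta = .run_meta(cfg))
}

.run_meta <- function(cfg) {
  list(package = "mrmediate",
       version = as.character(utils::packageVersion("mrmediate")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = cfg$seed, config = unclass(cfg))
}

#' Two-step mediation stage
#'
#' Mirrors the two-step order: mediators are first screened for a
#' significant mediator -> outcome IVW effect (and dropped when their
#' Egger-intercept test indicates pleiotropy); exposures enter only when
#' their total effect on the outcome was significant after FDR; the
#' exposure -> mediator effect must then also be significant. Each
#' surviving pathway gets a bootstrap mediation row. Failures are contained
#' per pathway.
#'
#' @param cfg an [analysisConfig()] naming at least one mediator.
#' @param report the [ResultsReport-class] from [runUnivariable()].
#' @return the report with the mediation table (and any new failures)
#'   filled in.
#' @export
runMediation <- function(cfg, report) {
  stopifnot(inherits(cfg, "analysisConfig"), methods::is(report, "ResultsReport"))
  if (length(cfg$mediators) == 0L) return(report)
  ld <- if (!is.null(cfg$ld_table)) readLDTable(cfg$ld_table) else NULL
  outcome <- readSummaryStats(cfg$outcome$path, cfg$outcome$label,
                              columnMap = cfg$column_map)
  alpha <- cfg$mediation$screen_alpha
  univ <- report@univariable
  ivw_rows <- univ[univ$method %in% c("IVW", "Wald ratio"), , drop = FALSE]
  sig_p <- ifelse(is.na(ivw_rows$pval_fdr), ivw_rows$pval, ivw_rows$pval_fdr)
  sig_exposures <- ivw_rows$exposure[sig_p < alpha]
  failures <- list(); rows <- list()

  ## step 1: screen mediators on the outcome
  mediator_fits <- list()
  for (mspec in cfg$mediators) {
    res <- tryCatch({
      m_instr <- .instruments_for(mspec, cfg, ld)
      hset_my <- harmonizeTables(m_instr, outcome, cfg$ambiguity_band)
      fit <- mrIVW(hset_my)
      if (fit@pval >= alpha)
        stop("mediator effect on outcome not significant (p = ",
             signif(fit@pval, 3), ")", call. = FALSE)
      if (nPairs(hset_my) >= 3L) {
        plei <- eggerInterceptTest(hset_my)
        if (plei@pval < 0.05)
          stop("mediator shows directional pleiotropy on the outcome ",
               "(Egger intercept p = ", signif(plei@pval, 3), ")",
               call. = FALSE)
      }
      list(fit = fit, table = readSummaryStats(mspec$path, mspec$label,
                                               columnMap = cfg$column_map))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      .log(cfg, "warn", "mediator ", mspec$label, " excluded: ",
           conditionMessage(res))
      failures[[length(failures) + 1L]] <-
        data.frame(stage = "mediation", unit = mspec$label,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else mediator_fits[[mspec$label]] <- res
  }

  ## step 2: exposure -> mediator, then the pathway bootstrap
  for (espec in cfg$exposures) {
    if (!(espec$label %in% sig_exposures)) {
      .log(cfg, "info", espec$label,
           " excluded from mediation (total effect not significant)")
      next
    }
    e3row <- ivw_rows[ivw_rows$exposure == espec$label, ][1, ]
    for (mlabel in names(mediator_fits)) {
      res <- tryCatch({
        mfit <- mediator_fits[[mlabel]]
        e_instr <- .instruments_for(espec, cfg, ld)
        hset_xm <- harmonizeTables(e_instr, mfit$table, cfg$ambiguity_band)
        fit_xm <- mrIVW(hset_xm)
        if (fit_xm@pval >= alpha)
          stop("exposure effect on mediator not significant (p = ",
               signif(fit_xm@pval, 3), ")", call. = FALSE)
        med <- bootstrapMediation(
          fit_xm@beta, fit_xm@se, mfit$fit@beta, mfit$fit@se,
          e3row$beta, e3row$se, B = cfg$mediation$B,
          seed = .child_seed(cfg$seed, 13L),
          labels = c(espec$label, mlabel, cfg$outcome$label))
        data.frame(pathway = sprintf("%s -> %s -> %s", espec$label, mlabel,
                                     cfg$outcome$label),
                   beta1 = fit_xm@beta, beta2 = mfit$fit@beta,
                   beta3 = e3row$beta,
                   indirect = med@indirect,
                   indirect_ci_low = med@ciIndirect[1],
                   indirect_ci_high = med@ciIndirect[2],
                   proportion_pct = 100 * med@proportion,
                   proportion_ci_low_pct = 100 * med@ciProportion[1],
                   proportion_ci_high_pct = 100 * med@ciProportion[2],
                   pval = med@pval, stringsAsFactors = FALSE)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        .log(cfg, "warn", "pathway ", espec$label, " -> ", mlabel,
             " skipped: ", conditionMessage(res))
        failures[[length(failures) + 1L]] <-
          data.frame(stage = "mediation",
                     unit = paste(espec$label, "->", mlabel),
                     reason = conditionMessage(res), stringsAsFactors = FALSE)
      } else rows[[length(rows) + 1L]] <- res
    }
  }
  report@mediation <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (length(failures))
    report@failures <- rbind(report@failures, do.call(rbind, failures))
  report
}

#' Run the full pipeline and write results
#'
#' Runs [runUnivariable()] then [runMediation()] and writes
#' `univariable.tsv`, `sensitivity.tsv`, `mediation.tsv`, `failures.tsv`
#' and `run.json` (run metadata: seed, package version, full config) into
#' the configured output directory. Output is a pure function of the input
#' files, config and seed.
#'
#' @param cfg an [analysisConfig()].
#' @return the final [ResultsReport-class], invisibly.
#' @export
runPipeline <- function(cfg) {
  report <- runUnivariable(cfg)
  report <- runMediation(cfg, report)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(cfg$outdir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(report@univariable, "univariable.tsv")
  wt(report@sensitivity, "sensitivity.tsv")
  wt(report@mediation, "mediation.tsv")
  wt(report@failures, "failures.tsv")
  jsonlite::write_json(report@meta, file.path(cfg$outdir, "run.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(report)
}

setMethod("show", "ResultsReport", function(object) {
  cat("ResultsReport:", nrow(object@univariable), "univariable rows,",
      nrow(object@mediation), "mediation rows,",
      nrow(object@failures), "failures\n")
})

## ---- command-line entry point -------------------------------------------

.cli_usage <- function() {
  cat("usage: mrmediate <subcommand> [--config FILE] [--seed INT]\n",
      "                [--outdir DIR] [--log-level LEVEL] [--preset]\n",
      "subcommands:\n",
      "  simulate   write a synthetic study (--outdir required; --preset\n",
      "             uses the coffee-CAC-scale preset)\n",
      "  mr         univariable MR + sensitivity (--config required)\n",
      "  mediate    full pipeline including two-step mediation (--config)\n",
      "  report     alias for mediate\n", sep = "")
}

.cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--preset") { opts$preset <- TRUE; i <- i + 1L; next }
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (!(key %in% c("config", "seed", "outdir", "log-level")))
      stop("unknown flag: ", a, call. = FALSE)
    if (i == length(args)) stop("flag ", a, " needs a value", call. = FALSE)
    opts[[gsub("-", "_", key)]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

#' Command-line entry point
#'
#' Thin shell over the pipeline functions; see `inst/scripts/mrmediate` for
#' the Rscript wrapper. Returns an exit status instead of quitting so it
#' can be tested in-process: 0 on success, 1 on a contained runtime error,
#' 2 on a usage error.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process's trailing arguments).
#' @return integer exit status, invisibly.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) { .cli_usage(); return(invisible(2L)) }
  sub <- args[1]
  opts <- tryCatch(.cli_opts(args[-1]), error = function(e) e)
  if (inherits(opts, "error") ||
      !(sub %in% c("simulate", "mr", "mediate", "report"))) {
    if (inherits(opts, "error")) message(conditionMessage(opts))
    else message("unknown subcommand: ", sub)
    .cli_usage()
    return(invisible(2L))
  }
  status <- tryCatch({
    seed <- if (!is.null(opts$seed)) as.integer(opts$seed) else 1L
    if (sub == "simulate") {
      if (is.null(opts$outdir)) stop("simulate needs --outdir", call. = FALSE)
      cfg <- if (isTRUE(opts$preset)) presetCoffeeCac(seed) else
        simulationConfig(seed = seed)
      writeStudy(simulateStudy(cfg), opts$outdir)
      0L
    } else {
      if (is.null(opts$config)) stop(sub, " needs --config", call. = FALSE)
      overrides <- list(file = opts$config, seed = seed)
      if (!is.null(opts$outdir)) overrides$outdir <- opts$outdir
      if (!is.null(opts$log_level)) overrides$log_level <- opts$log_level
      cfg <- do.call(analysisConfig, overrides)
      if (sub == "mr") {
        report <- runUnivariable(cfg)
        dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(report@univariable,
                           file.path(cfg$outdir, "univariable.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(report@sensitivity,
                           file.path(cfg$outdir, "sensitivity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      } else runPipeline(cfg)
      0L
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("needs --", conditionMessage(e)) ||
        grepl("config file not found", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}
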