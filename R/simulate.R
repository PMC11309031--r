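## Synthetic GWAS summary-statistics generator: exposure, mediator and
## outcome tables over a shared variant panel, with configurable causal
## effect, mediation structure and horizontal pleiotropy, plus the
## generating truth needed to score any estimator.

#' Simulation settings
#'
#' Defines a three-trait summary-level generative model over `J` exposure
#' instruments (per-SNP effect `gamma_j` on the exposure) and `JMed`
#' mediator-specific instruments (per-SNP effect `delta_j` on the mediator
#' only). Structural effects: exposure -> mediator `kappa`,
#' mediator -> outcome `thetaMed`, direct exposure -> outcome
#' `thetaDirect`, so the total exposure effect is
#' `thetaTotal = thetaDirect + kappa * thetaMed`. Per-SNP sampling
#' variances follow the standard GWAS approximation
#' `se = (2 N EAF (1 - EAF))^(-1/2)` for each trait's sample size.
#' Horizontal pleiotropy `alpha_j` on the outcome follows `pleiotropy`:
#' `none`, `balanced(tau)` (zero-mean), `directional(mu, tau)`, or
#' `inside_violated(rho)` (alpha correlated with gamma at correlation rho,
#' scaled by tau).
#'
#' @param J number of exposure instruments.
#' @param JMed number of mediator-specific instruments.
#' @param nX,nM,nY GWAS sample sizes for exposure, mediator, outcome.
#' @param thetaDirect,thetaMed,kappa structural effects (see above).
#' @param r2Exposure variance of the exposure explained by the J SNPs.
#' @param r2Mediator variance of the mediator explained by its JMed SNPs.
#' @param pleiotropy list with `type` in `c("none", "balanced",
#'   "directional", "inside_violated")` and fields `tau`, `mu`, `rho` as
#'   needed.
#' @param eafRange interval from which effect-allele frequencies are drawn.
#' @param palindromicFrac fraction of SNPs given palindromic (A/T or C/G)
#'   allele pairs.
#' @param ldBlocks optional list(`size`, `r2`) adding `size - 1` correlated
#'   companion SNPs per exposure instrument plus a matching LD table, to
#'   exercise clumping.
#' @param seed RNG seed.
#' @return a list of class `simulationConfig`.
#' @export
simulationConfig <- function(J = 26, JMed = 0, nX = 2e6, nM = 33000,
                             nY = 3000, thetaDirect = 0.4755,
                             thetaMed = 0.37, kappa = 0.85,
                             r2Exposure = 0.0085, r2Mediator = 0.06,
                             pleiotropy = list(type = "none"),
                             eafRange = c(0.05, 0.95),
                             palindromicFrac = 0, ldBlocks = NULL,
                             seed = 1L) {
  stopifnot(J >= 1, JMed >= 0, r2Exposure > 0, r2Exposure < 1,
            JMed == 0 || (r2Mediator > 0 && r2Mediator < 1),
            nX > J + 1, nM > J + 1, nY > J + 1,
            length(eafRange) == 2, eafRange[1] > 0, eafRange[2] < 1,
            eafRange[1] < eafRange[2],
            palindromicFrac >= 0, palindromicFrac <= 1)
  stopifnot(pleiotropy$type %in% c("none", "balanced", "directional",
                                   "inside_violated"))
  structure(list(J = as.integer(J), JMed = as.integer(JMed), nX = nX, nM = nM,
                 nY = nY, thetaDirect = thetaDirect, thetaMed = thetaMed,
                 kappa = kappa, r2Exposure = r2Exposure,
                 r2Mediator = r2Mediator, pleiotropy = pleiotropy,
                 eafRange = eafRange, palindromicFrac = palindromicFrac,
                 ldBlocks = ldBlocks, seed = seed),
            class = "simulationConfig")
}

#' Coffee-CAC-scale preset
#'
#' The study conditions used throughout the package's tests: J = 26
#' exposure instruments, total causal effect 0.79, exposure -> mediator
#' effect 0.85, mediator -> outcome effect 0.37 (hence direct effect
#' 0.79 - 0.85 x 0.37 = 0.4755 and true proportion mediated
#' 0.85 x 0.37 / 0.79 = 0.398), no pleiotropy. Sample sizes and variance
#' explained are calibrated so instruments are unambiguously
#' genome-wide-significant (mean per-SNP F about 650) and the exposure -> outcome
#' IVW standard error is about 0.2; see the methods vignette for the
#' calibration rationale.
#'
#' @param seed RNG seed carried into the config.
#' @return a `simulationConfig`.
#' @export
presetCoffeeCac <- function(seed = 1L) {
  simulationConfig(J = 26, JMed = 20, nX = 2e6, nM = 33000, nY = 3000,
                   thetaDirect = 0.79 - 0.85 * 0.37, thetaMed = 0.37,
                   kappa = 0.85, r2Exposure = 0.0085, r2Mediator = 0.06,
                   pleiotropy = list(type = "none"), seed = seed)
}

## allele pairs: draw non-palindromic by default, palindromic for a
## configurable fraction
.draw_alleles <- function(n, palindromicFrac) {
  pal <- stats::runif(n) < palindromicFrac
  ea <- character(n); oa <- character(n)
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  for (i in seq_len(n)) {
    if (pal[i]) {
      pr <- pal_pairs[[sample.int(4L, 1L)]]
    } else {
      repeat {
        pr <- sample(.NUCS, 2L)
        if (pr[2] != .revcomp(pr[1])) break
      }
    }
    ea[i] <- pr[1]; oa[i] <- pr[2]
  }
  data.frame(effect_allele = ea, other_allele = oa, stringsAsFactors = FALSE)
}

## effect magnitudes: a wide spread (real instrument panels mix a few
## strong loci with many modest ones; the spread also keeps the
## between-instrument variance well above the sampling variance, which
## MR-Egger needs), random signs, rescaled so the summed variance
## explained hits the target exactly
.draw_effects <- function(J, eaf, r2_target) {
  raw <- stats::runif(J, 0.25, 1.75) * sample(c(-1, 1), J, replace = TRUE)
  v <- sum(2 * raw^2 * eaf * (1 - eaf))
  if (v <= 0) stop("infeasible variance-explained target", call. = FALSE)
  raw * sqrt(r2_target / v)
}

## pleiotropic effects are defined relative to the exposure-increasing
## allele (directionality is only meaningful under an orientation
## convention, the same one MR-Egger uses), then signed back onto the
## as-generated allele coding; the returned vector is the realized
## per-SNP contribution to the outcome effect
.draw_pleiotropy <- function(reg, gamma) {
  J <- length(gamma)
  tau <- if (is.null(reg$tau)) 0 else reg$tau
  oriented <- switch(reg$type,
    none = numeric(J),
    balanced = stats::rnorm(J, 0, tau),
    directional = stats::rnorm(J, reg$mu, tau),
    inside_violated = {
      rho <- reg$rho
      ## alpha correlated with instrument strength |gamma| at correlation rho
      g <- (abs(gamma) - mean(abs(gamma))) / stats::sd(abs(gamma))
      tau * (rho * g + sqrt(1 - rho^2) * stats::rnorm(J))
    })
  sign(gamma) * oriented
}

#' Simulate a three-trait GWAS study
#'
#' Draws effect-allele frequencies, true per-SNP effects (rescaled so the
#' summed variance explained equals the configured target), and observed
#' effects with the standard per-SNP sampling variances, for the exposure,
#' mediator and outcome. Observed outcome effects follow
#' `by_j ~ N((thetaDirect + kappa thetaMed) gamma_j + thetaMed delta_j +
#' alpha_j, se_y^2)`. P-values are two-sided normal and exactly consistent
#' with `beta/se`. Deterministic for a fixed seed.
#'
#' @param cfg a [simulationConfig()].
#' @return a [SimulatedStudy-class]; its `truth` list holds `gamma`,
#'   `delta`, `alpha` (named per SNP), the structural parameters including
#'   `thetaTotal`, the instrument bookkeeping (`exposureSnps`,
#'   `mediatorSnps`), the config, and the LD table when `ldBlocks` is set.
#' @export
simulateStudy <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  .with_seed(cfg$seed, function() .simulate_study_impl(cfg))
}

.simulate_study_impl <- function(cfg) {
  J <- cfg$J; JM <- cfg$JMed
  n_core <- J + JM
  eaf <- stats::runif(n_core, cfg$eafRange[1], cfg$eafRange[2])
  gamma <- c(.draw_effects(J, eaf[seq_len(J)], cfg$r2Exposure), rep(0, JM))
  delta <- c(rep(0, J),
             if (JM > 0) .draw_effects(JM, eaf[J + seq_len(JM)], cfg$r2Mediator)
             else numeric(0))
  alpha <- c(.draw_pleiotropy(cfg$pleiotropy, gamma[seq_len(J)]), rep(0, JM))
  snp_id <- sprintf("rs%04d", seq_len(n_core))
  chrom <- as.character(((seq_len(n_core) - 1L) %% 22L) + 1L)
  pos <- 1e6 + ((seq_len(n_core) - 1L) %/% 22L) * 2.5e7

  ## optional LD blocks: companion SNPs tightly linked to each exposure
  ## instrument, sharing its true effect, with an explicit LD table
  ld_rows <- NULL
  if (!is.null(cfg$ldBlocks) && cfg$ldBlocks$size > 1L) {
    extra <- cfg$ldBlocks$size - 1L
    comp_of <- rep(seq_len(J), each = extra)
    comp_id <- sprintf("%s_ld%d", snp_id[comp_of],
                       rep(seq_len(extra), times = J))
    snp_id <- c(snp_id, comp_id)
    chrom <- c(chrom, chrom[comp_of])
    pos <- c(pos, pos[comp_of] + rep(seq_len(extra), times = J) * 1e4)
    eaf <- c(eaf, eaf[comp_of])
    gamma <- c(gamma, gamma[comp_of])
    delta <- c(delta, delta[comp_of])
    alpha <- c(alpha, alpha[comp_of])
    ## complete within-block LD so clumping sees every linked pair
    members <- split(c(snp_id[seq_len(J)], comp_id),
                     c(seq_len(J), comp_of))
    ld_rows <- do.call(rbind, lapply(members, function(ids) {
      pr <- t(utils::combn(ids, 2L))
      data.frame(snp_a = pr[, 1], snp_b = pr[, 2], r2 = cfg$ldBlocks$r2,
                 stringsAsFactors = FALSE)
    }))
    rownames(ld_rows) <- NULL
  }
  n_all <- length(snp_id)
  names(gamma) <- names(delta) <- names(alpha) <- snp_id

  alleles <- .draw_alleles(n_all, cfg$palindromicFrac)
  se_for <- function(n) 1 / sqrt(2 * n * eaf * (1 - eaf))
  make_table <- function(mu, n, label) {
    se <- se_for(n)
    beta <- stats::rnorm(n_all, mu, se)
    summaryStats(data.frame(
      snp_id = snp_id, chrom = chrom, pos_bp = as.integer(pos),
      effect_allele = alleles$effect_allele,
      other_allele = alleles$other_allele, eaf = eaf, beta = beta, se = se,
      pval = .z_pval(beta / se), n = n, stringsAsFactors = FALSE),
      traitLabel = label, sampleSize = n)
  }
  theta_total <- cfg$thetaDirect + cfg$kappa * cfg$thetaMed
  mu_y <- cfg$thetaDirect * gamma + cfg$thetaMed * (cfg$kappa * gamma + delta) +
    alpha
  study <- methods::new("SimulatedStudy",
    exposure = make_table(gamma, cfg$nX, "exposure"),
    mediator = make_table(cfg$kappa * gamma + delta, cfg$nM, "mediator"),
    outcome = make_table(mu_y, cfg$nY, "outcome"),
    truth = list(gamma = gamma, delta = delta, alpha = alpha,
                 thetaDirect = cfg$thetaDirect, thetaMed = cfg$thetaMed,
                 kappa = cfg$kappa, thetaTotal = theta_total,
                 exposureSnps = snp_id[gamma != 0],
                 mediatorSnps = snp_id[delta != 0],
                 ld = if (is.null(ld_rows)) NULL else ldTable(ld_rows),
                 config = cfg))
  study
}

setMethod("show", "SimulatedStudy", function(object) {
  tr <- object@truth
  cat("SimulatedStudy:", nVariants(object@exposure), "variants",
      sprintf("(%d exposure instruments, %d mediator instruments)\n",
              length(tr$exposureSnps), length(tr$mediatorSnps)))
  cat(sprintf("  thetaTotal = %.4g (direct %.4g + kappa %.4g x thetaMed %.4g)\n",
              tr$thetaTotal, tr$thetaDirect, tr$kappa, tr$thetaMed))
})

#' Write a simulated study to disk
#'
#' Writes the three summary TSVs (`exposure.tsv`, `mediator.tsv`,
#' `outcome.tsv`), a `truth.tsv` manifest with every per-SNP `gamma`,
#' `delta` and `alpha`, a `params.yaml` with the structural parameters, and
#' `ld.tsv` when an LD table was generated. Re-reading the TSVs through
#' [readSummaryStats()] reproduces the in-memory tables.
#'
#' @param study a [SimulatedStudy-class].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
writeStudy <- function(study, dir) {
  stopifnot(methods::is(study, "SimulatedStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeSummaryStats(study@exposure, file.path(dir, "exposure.tsv"))
  writeSummaryStats(study@mediator, file.path(dir, "mediator.tsv"))
  writeSummaryStats(study@outcome, file.path(dir, "outcome.tsv"))
  tr <- study@truth
  utils::write.table(
    data.frame(snp_id = names(tr$gamma), gamma = unname(tr$gamma),
               delta = unname(tr$delta), alpha = unname(tr$alpha)),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- tr$config
  yaml::write_yaml(list(thetaDirect = tr$thetaDirect, thetaMed = tr$thetaMed,
                        kappa = tr$kappa, thetaTotal = tr$thetaTotal,
                        J = cfg$J, JMed = cfg$JMed, nX = cfg$nX, nM = cfg$nM,
                        nY = cfg$nY, r2Exposure = cfg$r2Exposure,
                        r2Mediator = cfg$r2Mediator,
                        pleiotropy = cfg$pleiotropy, seed = cfg$seed),
                   file.path(dir, "params.yaml"))
  if (!is.null(tr$ld))
    utils::write.table(tr$ld@table, file.path(dir, "ld.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}
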