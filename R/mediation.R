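## Two-step MR mediation: indirect effect beta1 * beta2, proportion
## mediated beta1 * beta2 / beta3, parametric-bootstrap uncertainty.

#' Indirect effect of a mediation pathway
#'
#' Product of the exposure-to-mediator effect (`beta1`) and the
#' mediator-to-outcome effect (`beta2`).
#'
#' @param beta1 exposure -> mediator effect.
#' @param beta2 mediator -> outcome effect.
#' @return `beta1 * beta2`.
#' @examples
#' indirectEffect(0.85, 0.37)
#' @export
indirectEffect <- function(beta1, beta2) beta1 * beta2

#' Proportion of the total effect mediated
#'
#' `beta1 * beta2 / beta3`, where `beta3` is the total
#' exposure -> outcome effect. Scale-consistent: rescaling the mediator
#' (beta1 -> c beta1, beta2 -> beta2 / c) leaves the proportion unchanged.
#'
#' @inheritParams indirectEffect
#' @param beta3 total exposure -> outcome effect (must be nonzero).
#' @return the proportion mediated (a fraction; multiply by 100 for %).
#' @examples
#' proportionMediated(0.85, 0.37, 0.79)
#' @export
proportionMediated <- function(beta1, beta2, beta3) {
  if (any(beta3 == 0))
    stop("total effect beta3 is zero: proportion mediated undefined",
         call. = FALSE)
  beta1 * beta2 / beta3
}

#' Parametric bootstrap for a mediation pathway
#'
#' Draws `beta1*`, `beta2*`, `beta3*` independently from normal
#' distributions centred at the estimates with their standard errors,
#' recomputes the indirect effect and proportion mediated for each draw,
#' and reports bootstrap SDs as standard errors with 2.5/97.5 percentile
#' intervals. The pathway p-value is the two-sided normal p of
#' `indirect / se_indirect` (the proportion's distribution is heavy-tailed
#' when `beta3` is imprecise). If more than 1% of `beta3*` draws are
#' numerically zero the proportion results are flagged unstable.
#'
#' @param beta1,se1 exposure -> mediator estimate and SE.
#' @param beta2,se2 mediator -> outcome estimate and SE.
#' @param beta3,se3 total exposure -> outcome estimate and SE.
#' @param B bootstrap draws (minimum 1000).
#' @param seed RNG seed; fixed seed gives a bit-identical result.
#' @param labels character(3): exposure, mediator, outcome names.
#' @return a [MediationResult-class].
#' @export
bootstrapMediation <- function(beta1, se1, beta2, se2, beta3, se3,
                               B = 10000, seed = 1L,
                               labels = c("exposure", "mediator", "outcome")) {
  stopifnot(B >= 1000, se1 >= 0, se2 >= 0, se3 >= 0)
  if (beta3 == 0)
    stop("total effect beta3 is zero: proportion mediated undefined",
         call. = FALSE)
  draws <- .with_seed(seed, function() {
    b1 <- stats::rnorm(B, beta1, se1)
    b2 <- stats::rnorm(B, beta2, se2)
    b3 <- stats::rnorm(B, beta3, se3)
    list(ind = b1 * b2, prop = b1 * b2 / b3, near0 = mean(abs(b3) < 1e-8))
  })
  unstable <- draws$near0 > 0.01
  if (unstable)
    warning("more than 1% of bootstrap beta3 draws are ~0; ",
            "proportion-mediated results are unstable", call. = FALSE)
  indirect <- indirectEffect(beta1, beta2)
  proportion <- proportionMediated(beta1, beta2, beta3)
  se_ind <- stats::sd(draws$ind)
  qs <- function(x) unname(stats::quantile(x, c(0.025, 0.975), names = FALSE))
  pval <- if (se_ind > 0) .z_pval(indirect / se_ind) else
    as.numeric(indirect == 0)  # degenerate bootstrap: point mass
  if (pval == 0) pval <- .Machine$double.xmin
  methods::new("MediationResult", labels = labels,
               inputs = c(beta1 = beta1, se1 = se1, beta2 = beta2, se2 = se2,
                          beta3 = beta3, se3 = se3),
               indirect = indirect, proportion = proportion,
               seIndirect = se_ind, seProportion = stats::sd(draws$prop),
               ciIndirect = qs(draws$ind), ciProportion = qs(draws$prop),
               pval = pval, B = as.integer(B),
               seed = as.numeric(if (is.null(seed)) NA else seed),
               unstable = unstable)
}

setMethod("show", "MediationResult", function(object) {
  cat(sprintf("Mediation: %s -> %s -> %s\n", object@labels[1],
              object@labels[2], object@labels[3]))
  cat(sprintf("  indirect effect %.3f (95%% CI %.3f to %.3f)\n",
              object@indirect, object@ciIndirect[1], object@ciIndirect[2]))
  cat(sprintf("  proportion mediated %.2f%% (95%% CI %.2f to %.2f%%), p = %.3g\n",
              100 * object@proportion, 100 * object@ciProportion[1],
              100 * object@ciProportion[2], object@pval))
  if (object@unstable) cat("  (flagged unstable: beta3 bootstrap draws near zero)\n")
})

#' Two-step MR mediation from three harmonized sets
#'
#' Estimates `beta1` (exposure -> mediator), `beta2`
#' (mediator -> outcome) and `beta3` (total exposure -> outcome) by
#' multiplicative random-effects IVW on the three harmonized sets, then
#' runs [bootstrapMediation()].
#'
#' @param hsetXM exposure -> mediator [HarmonizedSet-class].
#' @param hsetMY mediator -> outcome [HarmonizedSet-class].
#' @param hsetXY exposure -> outcome [HarmonizedSet-class].
#' @param B,seed bootstrap settings (see [bootstrapMediation()]).
#' @return a [MediationResult-class].
#' @export
twoStepMediation <- function(hsetXM, hsetMY, hsetXY, B = 10000, seed = 1L) {
  e1 <- mrIVW(hsetXM)
  e2 <- mrIVW(hsetMY)
  e3 <- mrIVW(hsetXY)
  bootstrapMediation(e1@beta, e1@se, e2@beta, e2@se, e3@beta, e3@se,
                     B = B, seed = seed,
                     labels = c(hsetXM@exposureLabel, hsetXM@outcomeLabel,
                                hsetXY@outcomeLabel))
}
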