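---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
author: "mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure $X$ (here: coffee consumption) on an outcome $Y$ (coronary artery
calcification, CAC) from GWAS summary statistics measured in two
non-overlapping cohorts. For each instrument SNP $j$ we observe the per-allele
exposure association $\hat\beta_{Xj}$ with standard error $\sigma_{Xj}$ and
the outcome association $\hat\beta_{Yj}$ with $\sigma_{Yj}$. A valid
instrument is associated with the exposure, independent of confounders, and
affects the outcome only through the exposure; under those assumptions every
per-SNP Wald ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal
effect $\theta$.

The estimator suite mirrors standard MR practice:

* **IVW (multiplicative random effects)** — the primary estimator: weighted
  regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin with
  weights $1/\sigma_{Yj}^2$, i.e.
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j \hat\beta_{Xj}^2$.
  The fixed-effect standard error $(\sum w_j\hat\beta_{Xj}^2)^{-1/2}$ is
  multiplied by $\max(1, \sqrt{\hat\phi})$, where
  $\hat\phi = Q/(J-1)$ is the residual overdispersion; the floor at 1 means
  the reported interval is never narrower than the fixed-effect one, and
  $\hat\phi$ is recorded on the estimate (`scalePhi`).
* **MR-Egger** — the same regression with a free intercept, after orienting
  every pair so the exposure effect is positive (Egger regression is not
  invariant to allele coding, so a deterministic convention is required).
  The slope is consistent under InSIDE even with directional pleiotropy; the
  intercept estimates the average directional pleiotropic effect and is the
  pleiotropy test. Standard errors are inflated by the residual scale when
  it exceeds one; inference uses $t_{J-2}$.
* **Weighted median** — the inverse-variance-weighted median of the Wald
  ratios, interpolating the midpoint cumulative-weight function at 0.5 (a
  SNP carrying more than half the weight dictates the estimate outright).
  Consistent when at least half the weight lies on valid instruments.
* **Simple / weighted mode** — the maximum of a Gaussian kernel density over
  the Wald ratios, located on a 2001-point grid spanning the ratios plus
  three bandwidths, with bandwidth
  $h = \phi \cdot 0.9\,\min(\mathrm{SD}, \mathrm{MAD}) J^{-1/5}$. When the
  MAD degenerates to zero with distinct ratios, the SD is used; identical
  ratios return the common ratio. The weighted variant weights each kernel
  by the normalized inverse ratio variance.

The weighted-median and mode standard errors come from a seeded parametric
bootstrap: $B$ resamples of $(\hat\beta_{Xj}, \hat\beta_{Yj})$ from normal
distributions at the estimates with their standard errors, re-estimating
each time ($B = 1000$ by default; closed forms do not exist for the mode).
IVW p-values are normal, Egger p-values $t_{J-2}$ — the conventional pairing.
All confidence intervals are 95%.

# Instrument selection and harmonization

Instruments pass three gates before estimation:

1. **Significance**: $p$ strictly below the threshold (default
   $5\times10^{-8}$; a per-exposure override supports the relaxed
   $5\times10^{-7}$ / $5\times10^{-6}$ conventions used when fewer than a
   handful of SNPs survive).
2. **Independence**: greedy LD clumping — repeatedly keep the most
   significant remaining SNP (ties broken by position, then identifier) and
   drop every SNP within the window (default 10,000 kb) whose $r^2$ with it
   is at or above the threshold (default 0.001). LD is consumed as a
   precomputed pairwise table; pairs absent from the table are treated as
   unlinked, so clumping without a table degrades to window pruning of
   explicitly-listed pairs only.
3. **Strength**: per-SNP variance explained
   $R^2_j = 2\hat\beta_{Xj}^2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)$ and
   $F_j = (N-2)\,R^2_j/(1-R^2_j)$; SNPs with $F_j < 10$ are excluded. The
   filter is applied per SNP ($K=1$) because the exclusion rule is per-SNP
   language; the joint $F$ over all $K$ instruments,
   $(N-K-1)/K \cdot R^2/(1-R^2)$, is also reported.

Harmonization expresses every outcome effect on the exposure's effect
allele: same-order alleles are kept, swapped alleles flip the sign (and
complement the frequency), and non-palindromic mismatches are re-compared on
the reverse-complement strand before being dropped. Palindromic SNPs (A/T,
C/G) carry no strand information in their labels, so orientation is decided
by allele frequency alone: if either table's frequency falls inside the
ambiguity band (default [0.30, 0.70]) or is missing, the SNP is dropped;
otherwise matching minor/major status keeps it and opposite status flips it.
The band is configurable; dropping the whole band is the conservative
reading of excluding SNPs whose forward strand cannot be determined.
Instruments absent from the outcome table are dropped rather than proxied,
and the exclusion log accounts for every exposure SNP, so
`pairs + exclusions = instruments` always holds.

# Sensitivity analyses

* **Cochran's Q** (IVW framework): $Q = \sum w_j (r_j - \hat\theta_{FE})^2$
  over Wald ratios $r_j$ with first-order weights
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, $\chi^2_{J-1}$. **Rücker's Q'**
  (Egger framework): the weighted residual sum of squares about the Egger
  fit, $\chi^2_{J-2}$; $Q' \le Q$ always (nested models, same weights).
* **Egger intercept test**: $t_{J-2}$ on the intercept, $p < 0.05$ read as
  directional pleiotropy.
* **MR-PRESSO**: the observed residual sum of squares about leave-one-out
  IVW fits is compared with its distribution over `nbSim` simulated
  datasets drawn from the no-pleiotropy model
  ($\beta^*_{Yj} \sim N(\hat\theta_{-j}\hat\beta_{Xj}, \sigma_{Yj}^2)$, each
  rescored with its own leave-one-out estimates). Monte-Carlo p-values use
  the add-one convention, so the global p is bounded below by
  $1/(\mathrm{nbSim}+1)$. Per-SNP outlier p-values are Bonferroni-adjusted
  by $J$ — note this means outlier flagging at threshold 0.05 is only
  *possible* when $\mathrm{nbSim} > J/0.05$ (with $J = 26$, the default
  1000 simulations suffice; 300 do not). The distortion test re-estimates
  IVW without the flagged outliers and compares the relative shift with a
  bootstrap of random same-size removals.

# Two-step mediation

With a mediator $M$ (body-mass index in the motivating analysis), the
pathway is quantified by three IVW estimates: $\beta_1$
(exposure $\to$ mediator, using the exposure's instruments), $\beta_2$
(mediator $\to$ outcome, using the *mediator's* instruments) and $\beta_3$
(total exposure $\to$ outcome). The indirect effect is
$\beta_1\beta_2$ and the proportion mediated $\beta_1\beta_2/\beta_3$.
Uncertainty comes from a parametric bootstrap: independent normal draws of
the three estimates, recomputing both quantities per draw; standard errors
are bootstrap SDs and intervals 2.5/97.5 percentiles. Independence of the
draws is an approximation justified by the non-overlapping source cohorts.
The pathway p-value is the normal test of the indirect effect rather than
the proportion, whose distribution is heavy-tailed when $\beta_3$ is
imprecise; when more than 1% of $\beta_3$ draws are numerically zero the
proportion results are flagged unstable. The pipeline gates pathways the
way the motivating design does: mediators must show a significant effect on
the outcome (and no Egger-intercept pleiotropy — the generic form of
excluding a pleiotropic mediator), exposures must have a significant total
effect, and the exposure $\to$ mediator effect must be significant.

# The synthetic-data generator

`simulateStudy()` emulates the summary statistics the analysis consumes —
no individual-level data are simulated, matching what two-sample MR can
ever see. For $J$ exposure instruments with true effects $\gamma_j$ and
$J_{med}$ mediator-specific instruments with effects $\delta_j$:

$$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2), \quad
  \hat\beta_{Mj} \sim N(\kappa\gamma_j + \delta_j, \sigma_{Mj}^2), \quad
  \hat\beta_{Yj} \sim N(\theta_{dir}\gamma_j +
      \theta_{med}(\kappa\gamma_j+\delta_j) + \alpha_j, \sigma_{Yj}^2)$$

with $\sigma = (2N\,\mathrm{EAF}(1-\mathrm{EAF}))^{-1/2}$ per trait, EAF
drawn uniformly on [0.05, 0.95], and p-values exactly $2\Phi(-|\beta/\sigma|)$.
The total causal effect is $\theta_{tot} = \theta_{dir} + \kappa\,\theta_{med}$
and the true proportion mediated $\kappa\,\theta_{med}/\theta_{tot}$.
Mediator-specific instruments exist because the two-step design estimates
the mediator-to-outcome effect with the mediator's own instruments; SNPs
acting on the mediator only through the exposure would estimate
$\theta_{tot}/\kappa$ instead of $\theta_{med}$. All SNPs appear in all
three tables, as in real cross-tabulated GWAS.

Design choices that matter:

* **Effect-size spread.** Instrument magnitudes are drawn
  $\mathrm{U}(0.25, 1.75)\times$ a common scale (then rescaled so the summed
  variance explained hits the target exactly). Real instrument panels mix a
  few strong loci with many modest ones; just as importantly, MR-Egger
  requires the *between-instrument* spread of exposure effects to dominate
  their sampling noise (high $I^2_{GX}$) — a panel of near-identical effects
  biases the Egger intercept through regression dilution no matter how the
  estimator is implemented.
* **Pleiotropy orientation.** Pleiotropic effects ($\alpha_j$: none,
  balanced, directional, or InSIDE-violating with correlation $\rho$ to
  instrument strength) are defined relative to the exposure-increasing
  allele and signed back onto the generated coding. "Directional" is only
  meaningful under an orientation convention — applied in a random allele
  coding it averages out and no intercept test could detect it.
* **No sample overlap** between the three simulated GWAS (independent
  noise), matching the cohort-selection strategy the design assumes.
* **LD-free by default** (post-clumping instruments are approximately
  independent); an optional block mode adds tightly linked companion SNPs
  with a complete within-block LD table to exercise clumping.

## The coffee-CAC-scale preset

`presetCoffeeCac()` fixes the study conditions used throughout the tests:
$J = 26$, $\theta_{tot} = 0.79$, $\kappa = 0.85$, $\theta_{med} = 0.37$
(so $\theta_{dir} = 0.4755$ and true proportion mediated
$0.85 \times 0.37 / 0.79 \approx 0.398$), no pleiotropy, $J_{med} = 20$.
Sample sizes and variance explained are calibrated as a package design
choice, balancing four competing requirements: the exposure GWAS
($N = 2{,}000{,}000$, $r^2 = 0.0085$) makes every instrument unambiguously
genome-wide-significant (mean per-SNP $F \approx 650$, minimum
$\approx 34$), keeping both the IVW regression-dilution bias
($\approx \theta/F$) and the Egger-intercept dilution an order of
magnitude below the Monte-Carlo resolution of the recovery tests; the
outcome GWAS ($N = 3{,}000$) gives an IVW standard error near 0.2, so the
true effect of 0.79 is detected with high power while intervals remain
realistically wide; and the mediator GWAS ($N = 33{,}000$, $r^2 = 0.06$)
is large enough for strong mediator instruments yet small enough that
exposure instruments (acting on the mediator through $\kappa$) stay below
genome-wide significance in the mediator table, keeping the two instrument
sets cleanly separated during selection.

## What the tests do and do not show

Simulation-based checks run at these problem sizes: 500 replicates for
parameter recovery and Egger type-I error, 200 for PRESSO calibration
(`nbSim = 300`) and the weighted-median robustness contrast, 150 for
bootstrap-coverage checks — sizes at which Monte-Carlo error is small
relative to the asserted bands. Recovery of the proportion mediated is
asserted on the replicate *median*: the plug-in ratio
$\hat\beta_1\hat\beta_2/\hat\beta_3$ has mean biased upward by roughly
$\mathrm{SE}_3^2/\beta_3^2$ for any estimator, while its median is stable
because medians commute with the monotone map $1/\beta_3$.

The generator draws effects from normal sampling distributions with exactly
correct standard errors and no LD beyond the optional blocks, no allele
mis-coding, no population stratification, no winner's-curse ascertainment
of effect sizes, and no sample overlap. Passing tests therefore demonstrate
correctness of the estimators and pipeline under the model the methods
assume — not robustness to the many ways real GWAS data violate it.

# Numerical conventions

* P-values are two-sided and floored at the smallest positive double;
  Monte-Carlo p-values use the add-one convention.
* Clumping ties (equal p) break by genomic position then identifier, making
  the procedure deterministic under row permutation.
* Every stochastic routine (bootstraps, PRESSO, the generator) takes a seed
  and restores the caller's RNG state; pipeline stages derive child seeds
  deterministically from the single run seed, so a run is a pure function
  of (inputs, config, seed).
* Degenerate inputs have defined behaviour: a single instrument reduces the
  suite to the Wald ratio (logged downgrade); identical ratios give a zero
  bandwidth and return the common ratio; an exposure effect of exactly zero
  is a degenerate-instrument error; outlier removal leaving fewer than two
  SNPs is a degenerate-correction error.

# Known limitations

* No proxy-SNP lookup, multivariable MR, Steiger filtering, or non-linear
  (J/U-shaped) dose-response modelling.
* LD is consumed, never estimated; there is no reference-panel machinery.
* The binary-outcome case (e.g. hypertension as a mediator) is treated on
  the log-odds scale like any continuous trait; liability-scale subtleties
  are out of scope.
* Bootstrap independence of $\beta_1, \beta_2, \beta_3$ ignores any residual
  cross-cohort correlation.
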