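---
title: "Linking single-item symptom measures to the PROMIS T-score metric"
author: "prolink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking single-item symptom measures to the PROMIS T-score metric}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolink)
```

## The problem

Cancer symptom studies use a patchwork of patient-reported outcome (PRO)
instruments: 0–10 numeric rating scales (NRS), the 1–5 PRO-CTCAE adverse-event
items, and multi-item PROMIS short forms. Comparing results across studies
needs a common metric. The established solution is item response theory (IRT)
linking under a *single-group design*: one sample answers all instruments, the
PROMIS items act as **anchors** whose previously calibrated parameters define
the metric, and the single-item **targets** are calibrated onto that metric.
Each target then gets a *crosswalk table* mapping every raw score to a PROMIS
T-score (mean 50, SD 10 in the general adult reference population).

`prolink` implements this pipeline end to end: graded-response-model (GRM)
calibration, two linking routes, crosswalk construction, and the screens that
justify linking in the first place. It also ships the published item
parameters of five NRS and fifteen PRO-CTCAE symptom items, from which the
published concordance tables can be regenerated exactly
(`published_crosswalks()`).

## The measurement model

All items are modelled with Samejima's graded response model on the logistic
metric, with no 1.7 scaling constant (the convention in which the packaged
parameters are expressed). For an item with discrimination $a$ and ordered
category boundaries $b_1 < \dots < b_{K-1}$, the boundary curves are

$$P^*_k(\theta) = \frac{1}{1 + e^{-a(\theta - b_k)}},\qquad
P^*_0 \equiv 1,\; P^*_K \equiv 0,$$

and category probabilities are successive differences
$P_k(\theta) = P^*_{k-1}(\theta) - P^*_k(\theta)$. Category codes are 0-based
internally; readers map instrument-native codes (PRO-CTCAE 1–5 becomes 0–4,
the offset is restored for display). One NRS sleep-quality item is keyed
opposite to its domain and is reverse-coded (`reverse_code()`, an involution)
before calibration.

## Calibration

`grm_calibrate()` maximizes the marginal likelihood by EM, integrating the
latent trait over a fixed grid whose weights form the population prior. The
default grid — 101 equally spaced points on $[-6, 6]$ with standard-normal
weights — identifies the metric; it is deliberately wider than the $[-4, 4]$
range on which linking results are usually displayed, so that the posteriors
of extreme scores are not clipped.

The E-step computes each respondent's posterior over the grid; the M-step
maximizes the expected complete-data log-likelihood item by item with BFGS on
an unconstrained reparameterization (log-slope; first threshold plus
log-gaps), which guarantees a positive slope and strictly ordered thresholds
without constrained optimization. Analytic gradients keep the M-step cheap.
Convergence is declared when no parameter moves by more than $10^{-4}$
(default; `grm_control()`), capped at 500 cycles. Missing responses simply
drop out of the person likelihood (ignorable missingness; the generator's
missingness is MCAR, so this is exact for simulated data). Standard errors of
item parameters are not computed — crosswalk uncertainty comes from score
posteriors instead.

Two linking routes are supported:

* **Fixed-anchor calibration**: anchor items are frozen at their established
  parameters in every M-step; the freely estimated targets land directly on
  the anchor metric.
* **Concurrent calibration + Stocking–Lord**: everything is estimated freely
  (metric fixed only by the N(0,1) prior), then `stocking_lord()` finds the
  linear transformation $\theta^* = A\theta + B$ minimizing the weighted
  squared distance between the anchors' reference test characteristic curve
  (TCC) and the transformed free TCC. Under that transformation slopes divide
  by $A$ and thresholds map to $Ab + B$ (`transform_params()`). The criterion
  uses 49 points on $[-4, 4]$ weighted by the standard-normal density — the
  range over which agreement is conventionally judged; both grid and weights
  are configurable because published applications do not always state their
  weighting. Only the forward criterion is used (matching the reference TCC),
  not a symmetrized version. Optimization is Nelder–Mead from $(1, 0)$ with
  $A$ log-parameterized, followed by a BFGS polish; the result is never worse
  than the identity start.

When both routes are run, `compare_linking_methods()` tabulates the absolute
TCC difference of the target items at 0.1-$\theta$ resolution on $[-4, 4]$. A
maximum below one raw-score point is the conventional benchmark for declaring
the linking robust to the choice of method; the package's acceptance suite
reproduces this property on synthetic single-group cohorts.

## Crosswalk construction

`summed_score_likelihoods()` implements the Lord–Wingersky recursion:
$P(\text{summed score}=s \mid \theta_q)$ built by convolving item category
probabilities one item at a time. The test suite proves it identical (to
$10^{-12}$) to brute-force enumeration of all response patterns for small item
sets. `summed_score_eap()` then forms, for each score, the posterior over the
grid (grid weights = prior), and `build_crosswalk()` reports
$T = 50 + 10\,\hat\theta_{EAP}$ with SE $= 10 \times$ posterior SD — the
standard summed-score EAP convention for the parenthetical SE printed in
concordance tables.

Numerical choices: the scoring prior is the standard normal on the
anchor-linked metric (the identification prior of the anchor calibration);
mean and SD are configurable to probe sensitivity. Doubling the grid from 101
to 201 points moves no packaged T-score by more than 0.05 T-units (tested).
Full precision is kept internally; one-decimal rounding happens only in
`print()`/file output. Pattern-level EAP scoring of multi-item forms is out of
scope — single-item measures make the summed score sufficient anyway.

## Linking-assumption screens

`assumption_report()` bundles the three standard screens for one domain:

* **Correlation**: Pearson correlation between each target's raw score and
  the anchor summed score, on pairwise-complete observations. The
  conventional lower bound for linkable scores is .75. The rule is
  *advisory* by default (`block_low_correlation = FALSE`): published linking
  practice has accepted correlations slightly below the bound when all other
  evidence supported linking, so the package reports the flag and leaves the
  decision visible rather than silently dropping measures.
* **Subgroup invariance**: standardized mean differences (smd; focal minus
  reference over pooled SD) by gender (female − male) and by age (≥ 60 vs
  < 60, the split used in the published study; configurable). A measure is
  excluded when its smd differs from the anchor's smd by *strictly more than*
  0.10 in any split. The literature states the similarity rule as "≤ 0.10"
  and the flagging rule as "at least 0.11 away"; these agree only under the
  strict-inequality reading, which is the default here (the threshold is a
  parameter for anyone preferring the looser reading).
* **Unidimensionality**: $\omega_h$, the proportion of total score variance
  attributable to a general factor, computed from polychoric correlations via
  principal-axes factoring, an oblique rotation, a higher-order factor of the
  factor correlations, and a Schmid–Leiman orthogonalization:
  $\omega_h = (\sum_i g_i)^2 / \sum_{ij} R_{ij}$. Values ≥ .70 support
  treating the combined item set as unidimensional. Three group factors are
  extracted by default (two is available where a two-cluster solution is more
  natural). The oblique rotation is **promax** — the oblique method shipped
  with base R. The common default in dedicated factor-analysis packages is
  oblimin; with a dominant general factor the Schmid–Leiman general loadings,
  and hence $\omega_h$, are insensitive to the choice within the oblique
  family, and avoiding a rotation dependency keeps the package's footprint to
  base R plus recommended packages. Degenerate cases are handled explicitly:
  communalities are clipped at 0.995 with a warning (Heywood), and group
  factors with no loading (perfectly unidimensional input) are dropped, in
  which case $\omega_h$ comes directly from the single principal-axes factor.
  A full confirmatory factor analysis with WLSMV estimation and CFI/TLI/SRMR
  indices is deliberately out of scope; $\omega_h$ is the implemented
  unidimensionality surface.

Polychoric correlations use the two-step estimator (thresholds from the
margins, then univariate ML for the latent correlation), with bivariate-normal
cell probabilities computed by Gauss–Legendre quadrature; the test suite
checks the cells against an independent multivariate-normal implementation to
$10^{-9}$ and the estimator against generating correlations in simulation.

## The synthetic cohort generator

The raw respondent-level data behind the packaged parameters are not publicly
distributable, so validation runs on synthetic cohorts
(`simulate_cohort()`): $\theta_i \sim N(\mu + \text{subgroup shift}, \sigma)$,
responses drawn from the GRM, covariates emulating the observed-study
demographics (61% female; age normal with mean 56.4, SD 12.5, truncated to
18–89 — used only to form subgroups). Optional features: MCAR missingness,
subgroup latent mean shifts, and uniform DIF (a constant added to one item's
thresholds in one subgroup) — enough to exercise the smd screen, which is the
mechanism the screens are designed to catch. The previously established PROMIS
anchor calibrations are also not redistributable, so `make_anchor_bank()`
generates plausible 5-category anchors (slopes 1.5–4.5, threshold midpoints
spread over $[-1.5, 2.5]$), deterministic per seed.

What passing these tests shows — and does not show. The generator matches the
analysis model exactly: unidimensional latent trait, logistic GRM, normal
population, MCAR missingness. Parameter-recovery and method-agreement results
on this data validate the *implementation*, not the model's adequacy for any
real dataset; real PRO data bring multidimensionality, response styles,
mode-of-administration effects and informative missingness that the generator
deliberately does not emulate. Anchor-dependent quantities (correlations with
anchor scores, anchor smds) are therefore validated in distribution only,
never against published values.

## Validation problem sizes

The shipped test and acceptance suites use: recovery harnesses at $n = 2000$
(8 anchors + 3 five-category targets, five seeds; mean absolute error bounds
0.15 on slopes, 0.10 on thresholds); method-agreement at $n = 2000$ with the
full published anxiety item set; $\omega_h$ at $n = 5000$; polychoric
recovery at $n = 5000$; and the complete regeneration of all 120 published
concordance cells from the packaged parameters, each matched within ±0.5
T-units (both T-score and SE) — the agreement is in fact better than 0.25
throughout. These sizes keep a full run around a minute on one CPU while
leaving the statistical bounds comfortably testable.

## Known limitations

* The latent density is fixed at the (discretized) normal prior in both
  calibration and scoring; empirical-histogram priors are not estimated.
* No item-parameter standard errors or IRT-based DIF tests (the smd screen is
  the implemented invariance surface).
* Linking is strictly unidimensional, single-group, Stocking–Lord; Haebara
  and moment-based methods are not provided.
* `published_crosswalks()` regenerates tables from the packaged parameters
  under the package's scoring conventions; agreement with the originally
  printed cells is bounded by those conventions (scoring prior, grid) and by
  the two-decimal rounding of the published parameters.
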