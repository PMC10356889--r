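---
title: "Statistical methods for CBMN radiation biodosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for CBMN radiation biodosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbmndose)
```

## The assay and the model

In the cytokinesis-block micronucleus (CBMN) assay, cultured lymphocytes are
arrested at cytokinesis with cytochalasin B so that cells that completed one
division appear binucleated (BN). Radiation-induced chromosome damage shows
up as micronuclei (MN) — small chromatin bodies formed from acentric
fragments or lagging chromosomes — inside those BN cells. The scoring unit
is the BN cell; the data for one dose point are a histogram: how many cells
carry 0, 1, 2, ... MN.

The dose–response of the MN yield per BN cell is linear-quadratic,

$$y(D) = c + \alpha D + \beta D^2,$$

with absorbed dose $D$ in Gy, spontaneous background $c$, a linear term
$\alpha$ dominating at low dose from single-track damage, and a quadratic
term $\beta$ from two-track exchanges that dominates at high acute doses.
All three coefficients are physically non-negative and the fit is
constrained accordingly.

## Calibration fitting

`fit_lq()` maximises the aggregated Poisson log-likelihood

$$L(c, \alpha, \beta) = \sum_i \left[ M_i \ln \lambda_i - N_i \lambda_i \right],
\qquad \lambda_i = c + \alpha D_i + \beta D_i^2,$$

where $N_i$ is the number of BN cells and $M_i$ the total MN count at dose
$D_i$. For Poisson-distributed per-cell counts this aggregate likelihood is
equivalent to the per-cell one for these parameters, and it only needs the
published-table totals. Per-dose dispersion indices in real CBMN data run
slightly above 1 (about 1.03–1.12 in the packaged table); this mild
overdispersion is deliberately ignored in fitting, which is the standard
practice of biological dosimetry curve fitting. The consequence is that
coefficient standard errors can be modestly optimistic relative to fitters
that rescale by a heterogeneity factor — one reason published standard
errors can exceed the inverse-Fisher-information ones reported here, and why
agreement with published coefficients should be judged on the coefficient
scale, not the SE scale.

Numerics: the optimiser is box-constrained quasi-Newton (L-BFGS-B) with the
analytic gradient, started deterministically from unweighted least squares
on $(D_i, M_i/N_i)$ clipped to $\ge 10^{-6}$. The likelihood is smooth and
three-dimensional, so convergence is essentially immediate; the convergence
control (`factr = 1e5`) corresponds to a relative log-likelihood change
around $10^{-11}$, far below the precision of any printed coefficient. If
the line search stalls at machine precision the candidate is accepted only
when the scaled gradient is numerically zero. The covariance is the inverse
observed Fisher information
$I_{jk} = \sum_i N_i x_{ij} x_{ik} / \lambda_i$, $x_i = (1, D_i, D_i^2)$,
at the optimum. Fits need at least three distinct doses (the model is
otherwise unidentifiable) and at least one MN overall.

`fit_lq(data, group = "sex")` refits per stratum, which is how sex-specific
curves are produced: females carry higher spontaneous MN frequencies (about
1.4–1.65-fold, increasing with age), so pooled backgrounds can be biased for
either sex.

## Dose estimation with merged errors

Given an observed count $M$ in $N$ cells, the point dose inverts the curve
in closed form (positive quadratic root; yields at or below background map
to 0 Gy — negative doses are meaningless). The 95% limits must combine two
error sources:

1. **Poisson counting error**: exact Garwood limits on $M$,
   $\tfrac{1}{2}\chi^2_{0.025}(2M)$ and $\tfrac{1}{2}\chi^2_{0.975}(2M+2)$
   (lower limit 0 when $M = 0$), divided by $N$ to give yield limits. A
   normal-approximation variant is available (`ci_method = "approx"`); exact
   is the default because validation samples can have small counts.
2. **Calibration-curve error**: the delta-method band
   $y(D) \pm 1.96\,\mathrm{se}(D)$, $\mathrm{se}(D) = \sqrt{x' V x}$ with
   $x = (1, D, D^2)$ and $V$ the coefficient covariance.

The curve-crossing construction merges them: the lower dose limit is the
smallest $D \ge 0$ where the *upper* band reaches the *lower* yield limit
(0 if the band at $D=0$ already exceeds it), and the upper limit is where
the *lower* band reaches the *upper* yield limit. Both bands are monotone
increasing here, so the crossings are found by `uniroot()` bisection to
$10^{-10}$ Gy on $[0, D_{max}]$ ($D_{max}$ = 10 Gy by default). A limit
beyond $D_{max}$ raises an error rather than silently truncating, and point
estimates beyond the calibrated dose range are flagged as extrapolated with
a warning.

Triage classification uses the point estimate alone against the 1.5 Gy
cutoff (the conventional threshold separating likely acute radiation
syndrome from lower exposures), with the cutoff itself in the low class —
each sample lands in exactly one bin, matching how triage cross-tabulations
are reported.

## Automated-scoring errors and their correction

Automated MN scorers make three kinds of error, all expressed per total
scored BN cell: false-positive BN cells (objects the scorer wrongly accepts
as BN cells), false-positive MN (spurious detections), and false-negative
MN (missed MN, found only on full manual review). Semi-automated correction
rejects FP BN cells and removes FP MN; manual correction additionally
restores FN MN. `correct_scoring()` applies these corrections to count
tables with a deterministic histogram rule: rejected BN cells leave from
the 0-MN class (over 97% of cells are MN-free at every calibrated dose, so
this is the overwhelmingly likely class, and the simulator can be told
otherwise), MN removals demote cells from the currently lowest MN-bearing
class, and MN additions promote cells from class 0 upward. Measured data
never record *which* cells gained or lost MN, so any total-preserving rule
is admissible; a deterministic one is testable, and the identities
`BN' = BN − FP_BN` and (manual) `MN' = MN − FP_MN + FN_MN` hold exactly.

Error rates between measured doses are piecewise-linearly interpolated with
flat tails (`build_error_model()`), not smoothed by a fitted trend: the
measured grid is sparse and non-monotone at low dose, and interpolation
stays faithful to it.

The range summaries in `summarize_error_rates()` are reported both with and
without the unirradiated 0 Gy row, because background scoring errors arise
from a different mechanism (no radiation-induced apoptosis) and published
range conventions differ on including it.

## The simulator

`simulate_study()` generates complete seeded experiments. Its defaults
emulate the design of the calibration study the fixtures come from: the
nine-point dose grid 0–4 Gy, on the order of 16,000–18,000 BN cells per
dose point, per-cell MN counts that are Poisson with mean $y(D)$ from the
generating curve, and blind validation samples of a few thousand cells at
coded doses. Options cover what the real assay adds on top of pure Poisson
scoring:

- **Overdispersion**: a gamma-mixed Poisson whose shape
  $\lambda/(d_t - 1)$ hits a target dispersion index $d_t$ (defaults to
  1.1, the upper range seen in real per-dose tables).
- **Scoring corruption** (`corrupt_scoring()`): binomial draws of the three
  error counts against a `scoring_error_model` at each row's dose —
  FN MN removed from randomly chosen MN (capped at availability, with the
  cap recorded), FP MN added to randomly chosen cells, FP BN cells appended
  MN-free by default (configurable to carry MN at the FP MN rate). The
  function returns the exact inspection record that undoes it, so the
  corruption/correction round trip restores totals identically — a property
  the tests exercise at every seed.
- **Donor structure**: background multipliers per donor (e.g. a 1.4-fold
  female background) are supported at the study level via stratified
  fitting; per-donor variance components beyond a baseline multiplier are
  not modelled, since published pooled tables provide no basis to calibrate
  them.

What passing simulation-based tests shows — and what it does not: the
generator reproduces the count statistics, the dose dependence of scoring
errors, and the direction of their bias on fitted curves (dose-increasing
FN rates depress high-dose yields and with them $\beta$). It does not
emulate image-level artefacts, donor age/lifestyle effects on background,
radiation-quality (RBE) differences between X- and γ-rays, or inter-donor
heterogeneity, so real-data performance can differ even when all synthetic
checks pass.

## Problem sizes and numerical checks

The test suite's stochastic checks use sizes chosen to make sampling noise
negligible relative to the asserted margins while keeping a full run fast:
500 replicates for 95%-interval coverage at 2 Gy (asserted ≥ 90%, leaving
room for simulation noise), 100 seeded fits for 3-SE parameter recovery
(asserted ≥ 95% per coefficient), 20 seeds for the corruption-bias
direction, and 200 replicates for the unit-dispersion property. Oracles are
independent of the code paths they check: a refined grid search for the
likelihood maximiser, bisection on the forward curve for inversion, a
$10^{-4}$ Gy grid scan for the confidence limits, and an identity-link
Poisson GLM as an external cross-check of the fitter.

## Known limitations

- Only the linear-quadratic model is offered — no linear-only or
  negative-binomial fits, no donor random effects.
- Confidence limits assume acute whole-body exposure; no partial-body or
  protracted-exposure corrections.
- The scoring-error model operates on per-cell rates, not images; inspection
  outcomes are inputs, never computed.
- Published per-sex raw distributions were not available, so sex-specific
  curves are supported mechanically (stratified fitting) but not validated
  against published per-sex coefficients.
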