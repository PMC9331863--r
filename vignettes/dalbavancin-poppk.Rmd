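---
title: "Population PK/PD of dalbavancin: model, simulation and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK/PD of dalbavancin: model, simulation and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dalbapk)
```

## The problem

Dalbavancin is a lipoglycopeptide active against MRSA and other resistant
Gram-positive organisms. Its distinguishing property is a terminal
half-life of several hundred hours, which makes once-weekly dosing
possible and has pushed real-world use well beyond the licensed skin
indication, into osteomyelitis, prosthetic-joint infection and
endocarditis — diseases treated for 4–6 weeks or longer. Two questions
then dominate clinical use: for a given dosing regimen and renal function,
**how many weeks does drug exposure stay optimal**, and **when should a
trough sample be drawn** so that an additional dose can be given before
exposure decays below target?

This package implements the full quantitative chain used to answer them:
a population pharmacokinetic model, the machinery to estimate and
evaluate such models on sparse therapeutic-drug-monitoring (TDM) data,
and a Monte Carlo probability-of-target-attainment (PTA) engine with a
TDM-timing rule.

## Structural and statistical model

Disposition follows a two-compartment linear mammillary model with
central-compartment elimination and constant-rate IV infusion input
(0.5 h by default; at weekly horizons the infusion duration is
immaterial, but it is configurable per dose event). The closed-form
during-/post-infusion solution is superposed over dose events; a
matrix-exponential solver over the full rate matrix provides the general
1/2/3-compartment path, and the two implementations cross-validate each
other to below 1e-6 relative error. Time is measured in hours since the
first dose: "day 8" is 168 h, "week k" is 168·k h.

The population layer is standard nonlinear mixed effects:

* typical values `θ = (θ_CL, θ_V1, θ_Q, θ_V2)`;
* creatinine clearance (CLcr, CKD-EPI, mL/min/1.73 m²) as covariate on
  clearance, default **uncentred exponential** form
  `CL = θ_CL · exp(β · CLcr)`. The published estimates only reconcile
  with this form (0.029 · exp(0.0043 · 93) ≈ 0.043 L/h, the reported
  median clearance), so it is the default; a centred power form
  `θ_CL · (CLcr/ref)^β` is available via `covariate_form = "power"`.
* log-normal inter-individual variability, `P_i = P_typ · exp(η_i)` with
  independent `η ~ N(0, ω²)` per parameter (diagonal Ω — correlations
  were reportedly tested and none retained). Reported IIV percentages
  are interpreted as `100·ω`; the alternative
  `ω = sqrt(log(1 + CV²))` differs by under 2 % at these magnitudes.
* proportional residual error `y = f · (1 + b·ε)` (b = 0.3392 in the
  final model), with additive and combined forms available.

`dalbavancin_model("final")` and `"base"` expose the published parameter
sets; `population_model()` builds arbitrary ones, and YAML round-trip
(`write_model()`/`read_model()`) keeps configurations editable.

## Estimation

`fit_population()` maximizes the marginal likelihood, integrating the
random effects per subject with a **Laplace approximation** at the
posterior mode of η (found by Nelder–Mead in compiled code, with a
finite-difference Hessian and Cholesky log-determinant). The original
analysis used SAEM in commercial software; this package contracts the
estimator's *behaviour* — marginal-likelihood maximization with a
documented approximation — and validates it by parameter recovery on
synthetic cohorts rather than by reproducing printed decimals, which
would require the original (unavailable) dataset. An importance-sampling
evaluation of the same likelihood (`marginal_loglik(..., method =
"importance")`) provides an internal cross-check; the two agree within
1 % on test cohorts.

Numerical choices that matter:

* Outer optimization is L-BFGS-B on log-transformed parameters. The
  covariate coefficient is estimated with a 0.01 parameter scale, and
  CLcr is centred at the cohort median *internally* (the uncentred
  intercept is an extrapolation to CLcr = 0 and sits on a flat ridge
  with β); the reported `θ_CL` is back-transformed exactly, with a
  delta-method standard error.
* The inner η-modes are re-found from zero at every objective
  evaluation, making the objective a deterministic function of the
  parameters — warm starts would leak state into finite-difference
  gradients.
* Box constraints keep `ω ≥ 0.001` and `b ≥ 0.005`; estimates at a bound
  are reported as such.
* BIC uses `n = number of observations` (`OFV + k·log(n)`), stated
  explicitly because mixed-effects software differs here; the LRT is the
  χ² upper tail of the OFV drop.
* Observations below the 0.5 mg/L LLOQ are discarded from fitting and
  flagged (M1). Trough concentrations in this indication sit far above
  the LLOQ, so the choice is essentially cosmetic.

With all four IIVs free on sparse trough-weighted data, the marginal
likelihood itself (not merely its Laplace approximation — importance
sampling confirms it) can prefer a degenerate ridge with a huge
peripheral volume and inflated `ω_CL`. The original study reported the
same qualitative finding: IIV was adequately estimated only for
clearance. Recovery work therefore fixes `ω_Q` and `ω_V2`
(`fix = c("omega_Q", "omega_V2")`), the standard sparse-data practice.

`screen_covariates()` correlates empirical-Bayes η's with covariates
(Pearson; point-biserial for binary) and proposes p < 0.05 candidates for
LRT inclusion. Note that empirical-Bayes shrinkage attenuates these
correlations: at 69 subjects with 3 samples each, power for the CLcr
effect is only moderate, which is worth remembering when interpreting a
negative screen. `map_estimate()` gives MAP individual parameters for TDM
interpretation; with proportional error the MAP mode tilts a few percent
from zero even for a perfectly typical observation, an O(b²) effect of
the prediction-dependent variance.

## Diagnostics

`vpc()` simulates replicate datasets at the original design and compares
observed 10th/50th/90th percentiles per quantile-based time bin (8 bins
by default, merged below 5 observations, edges retained in the result)
with the 90 % envelope of the same percentiles over replicates. `npde()`
implements the standard normalized-prediction-distribution-error
algorithm: per-subject simulation, decorrelation by the inverse Cholesky
factor of the empirical simulated covariance, rank of the decorrelated
observation mapped through `Φ⁻¹((r − 0.5)/K)`. The attached symmetry test
is the Wilcoxon signed rank against median zero (the published analysis
names no test; a t-test is available by option) plus Shapiro–Wilk for
normality. Under the generating model the pooled NPDE are N(0,1) to the
tolerances exercised in the test suite.

## The PTA engine and TDM timing

The pharmacodynamic target is total concentration ≥ 8.04 mg/L. The
arithmetic chain behind it: the efficacy driver is fAUC₂₄ₕ/MIC > 111.1
against *S. aureus*; with 7 % unbound fraction and the EUCAST breakpoint
MIC 0.125 mg/L, a constant total concentration C gives
`fAUC₂₄ₕ/MIC = 24 · 0.07 · C / 0.125`, which crosses 111.1 at
8.27 mg/L (`threshold_for_target()`). The slightly lower 8.04 mg/L
carried as the default originates in a prior probabilistic analysis
demanding ≥ 90 % probability of attainment; it is treated as a configured
constant, not re-derived.

`simulate_class()` draws 1000 subjects with CLcr **uniform** within the
renal class ([15,30), [30,60), [60,90), [90,120] by default), samples
individual parameters (IIV only — residual error is assay noise and is
excluded, since the target concerns true exposure), and evaluates
concentrations on the weekly grid, weeks 2–12. Attainment is judged at
the weekly time points; between-week excursions are not credited.
`optimal_duration()` returns the last week of the continuous run with
PTA ≥ 90 %, and `tdm_timing()` places the first TDM sample one week
before the expected end of coverage (`day = 7·(weeks − 1) ± 3`), with
"immediate TDM" advised when even week 2 fails.

The within-class covariate distribution is the one genuinely unknown
study condition: only class bounds are stated, and the cohort spanned
CLcr 3–141. Uniform sampling reproduces the published durations for the
approved regimens (2/2/2 weeks, 3 weeks for CLcr 30–59) and the
preserved-function double regimen (4 weeks) exactly; the double-regimen
cells for CLcr 30–59 and 60–89 sit almost exactly on the 90 % line at
their published final week (PTA ≈ 0.89–0.90), so simulated durations
there come out 5–6 and 4–5 weeks depending on the Monte Carlo seed — one
week of play that also propagates to the corresponding TDM day (28 vs 35)
and is why results are reported with a ±1-week reading. The simulated
week-6 5th–95th fold difference for CLcr 30–59 (≈ 5.9) runs some 15 %
above the published 5.13 for the same reason.

## The synthetic cohort

`generate_cohort()` emulates the study: 69 subjects; CLcr log-normal
(median 93, IQR 72–104) truncated to [3, 141]; weight, age, height and
albumin truncated normals matching the reported medians and ranges;
2–14 weekly doses (median 2, per the reported distribution) of 1000 or
1500 mg (1500 mg in ~80 % of subjects); 1–19 samples per subject
(median 3, negative-binomial), drawn after the second dose at
trough-like offsets of 5–9 days after a dose, with 10 % early
post-infusion peaks; proportional residual error; BLQ flagged below
0.5 mg/L. The true sampling-time design of the study is unpublished, so
these rules are explicit assumptions exposed in `cohort_config()` —
including `samples_range = 3:5`, the moderately rich design used for
parameter-recovery work. Ground-truth parameters are retained per
subject.

What passing tests on this cohort do **not** show about real data: the
generator has no inter-occasion variability, no covariate effects beyond
CLcr-on-CL, no model misspecification (the fitted structural model is the
generating one), and no informative sampling (times do not depend on
observed concentrations, whereas real TDM timing reacts to results).
Estimator performance on real cohorts will be no better than on this
idealization.

## Problem sizes and limitations

The test suite and the acceptance script run Monte Carlo sizes chosen for
desk-scale reproducibility: 1000 subjects per PTA scenario (matching the
published analysis), 200–1000 VPC/NPDE replicates, 10-seed recovery
ensembles on 69-subject cohorts, and 20-replicate BIC model-selection
experiments on 15-subject rich-design cohorts. Clearance-intercept
recovery is judged on the 10-seed ensemble mean (±15 %): the per-seed
maximum-likelihood spread on a 69-subject sparse design is ~20–25 % RSE,
so per-seed bounds that tight would test the seed, not the estimator.

Known limitations: no nonlinear elimination, oral absorption or tissue
compartments; no inter-occasion variability; no MIC-distribution-weighted
cumulative response; printed OFV/BIC values and the observed-data GOF
R² = 0.88 of the original analysis are functions of the unavailable
clinical dataset and are deliberately not targets.
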