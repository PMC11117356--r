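---
title: "Methods: population pharmacokinetics of meropenem in neonatal and pediatric ECMO/CRRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics of meropenem in neonatal and pediatric ECMO/CRRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoperem)
```

## The model

Meropenem disposition in critically ill neonates and children supported by
extracorporeal membrane oxygenation (ECMO), with or without continuous renal
replacement therapy (CRRT), is described by a one-compartment model with
zero-order (infusion) input and first-order elimination. The covariate model
anchors both clearance and volume to the cohort's median body weight of
7.88 kg and lets CRRT shift the volume:

$$CL_i = CL_p \cdot \frac{BW_i}{7.88} \cdot e^{\eta_{CL,i}}, \qquad
  V_i = V_p \cdot \frac{BW_i}{7.88} \cdot (1+\theta_{CRRT})^{CRRT_i}
        \cdot e^{\eta_{V,i}}$$

with independent, normally distributed subject-level random effects
$\eta_{CL} \sim N(0, \omega^2_{CL})$ and $\eta_V \sim N(0, \omega^2_V)$
(log-normal inter-individual variability, IIV), and a proportional residual
error: an observation $y_{ij}$ at predicted concentration $f_{ij}$ has
variance $\sigma^2 f_{ij}^2$.

The packaged estimates (`final_model()`) are $CL_p = 1.09$ L/h,
$V_p = 3.98$ L, $\theta_{CRRT} = 1.04$ (a CRRT multiplier of 2.04, i.e. an
approximate doubling of volume), $\omega^2_{CL} = 0.0887$,
$\omega^2_V = 0.916$ and $\sigma^2 = 0.17$. Two interpretation choices are
built in deliberately:

* the IIV rows are treated as **variances on the log scale** (the NONMEM
  convention), not coefficients of variation, and
* the proportional residual term 0.17 is a **variance** (residual SD about
  41% of the prediction); the "(17%)" printed next to it is the relative
  standard error of the estimate, not the error magnitude.

Concentrations from any infusion schedule are evaluated in closed form by
superposition: an event with rate $R$ and duration $D$ contributes
$\frac{R}{CL}(1-e^{-k_e \tau})$ while running ($\tau \le D$) and
$\frac{R}{CL}(1-e^{-k_e D}) e^{-k_e(\tau-D)}$ afterwards, with
$k_e = CL/V$. The closed form is verified in the tests against a numeric
ODE integration of $dC/dt = R(t)/V - k_e C$ to below $10^{-4}$ mg/L.
Concentrations are treated as total drug; no free-fraction correction is
applied for fT>MIC (meropenem protein binding is about 2%, so the
distinction is negligible at these tolerances).

## Dosing simulation and PTA

`pta()` and `run_table3()` evaluate the probability of target attainment
(PTA) for the standard regimens: 20 or 40 mg/kg every 8 h as 0.5 h or 3 h
infusions, and 60 or 120 mg/kg/day as a continuous infusion, each for a
typical subject (body weight 7.88 kg) on and off CRRT. For each of the
10,000 simulated subjects a steady-state concentration-time profile is
computed on an **hourly grid over the final 24 h of a 7-day course**, and
fT>MIC is the fraction of grid points strictly above the MIC; a subject
attains the target when that fraction reaches 40% or 100%.

Two simulation choices matter and are worth stating plainly:

* **Residual error is applied to the simulated grid concentrations**
  (`include_ruv = TRUE` by default): every grid point is perturbed by the
  proportional error before the fT>MIC comparison. Without observation-level
  noise a continuous infusion at steady state either always or never exceeds
  a given MIC, which cannot produce the intermediate PTA values published
  for the 100% target at low MICs; with per-point noise at the estimated
  residual magnitude those cells are reproduced closely (e.g. the
  120 mg/kg/day, MIC 0.5, 100% target cell simulates to ~81% against a
  printed 79%). The flag exposes the noiseless alternative, which is also
  the variant checked against a closed-form log-normal-clearance oracle in
  the tests.
* **Common random numbers**: all regimens within one `pta()` call share the
  same random-effect and residual draws. PTA is then exactly non-increasing
  in MIC and dose comparisons are paired, and a fixed seed reproduces the
  result bit for bit.

The grid convention has a visible consequence at extreme MICs under the
100% target: with 25 evaluation points and ~41% per-point noise, a subject
whose whole profile sits two- to three-fold above the MIC still fails the
"all points above" criterion with probability in the tens of percent. A
finer grid makes that row stricter and a coarser one more lenient, and no
single resolution reproduces every published cell simultaneously; the
hourly default is the coarsest grid consistent with the continuous-infusion
cells and is kept fixed rather than tuned per cell.

## Estimation

`fit_model()` maximises a Laplace approximation of the marginal likelihood:
for each subject the joint density of data and random effects is maximised
over $(\eta_{CL}, \eta_V)$ and corrected with the log-determinant of the
numeric Hessian at the mode. Implementation details that experience with
sparse therapeutic-drug-monitoring (TDM) data forced:

* **The inner problem can be multimodal.** With two to four observations a
  subject's conditional density over $(\eta_{CL}, \eta_V)$ regularly has two
  comparable modes (a fast-elimination and a slow-elimination explanation).
  The inner optimiser therefore scans a fixed 5x5 grid spanning plus/minus
  two prior standard deviations before running a damped Newton search, so
  the chosen basin does not depend on the optimisation path and the outer
  objective stays continuous. A purely warm-started inner search produced
  objective discontinuities of several units and stalled the outer
  optimiser.
* Predictions below $10^{-6}$ mg/L are floored in the proportional-error
  variance to avoid zero-variance singularities.
* Positivity is enforced by log transforms ($\log CL_p$, $\log V_p$, the
  variances) and $\log(1+\theta)$ for the categorical shift; transformed
  parameters are box-bounded at plus/minus 30 to keep degenerate noise-free
  fits from drifting to infinity.
* Outer starting values are literature magnitudes (CL 0.1 L/h/kg, V
  0.5 L/kg at the data's median weight) with jittered restarts; restarts
  draw from the session RNG, so seed the session for exact reproducibility.
* Relative standard errors come from the inverse numeric Hessian of the
  objective, delta-transformed to the natural scale.

The tests compare the Laplace objective with two independent quadrature
oracles: brute-force 32x32 Gauss-Hermite on a sparse toy set (agreement
within 0.1) and adaptive, mode-centred quadrature on richer small instances
(within 0.5). The remaining discrepancy is genuine approximation error of
the Laplace method, not optimiser failure.

`scm()` performs forward stepwise covariate selection: every remaining
covariate-parameter-form combination (continuous covariates in linear and
power forms, categorical ones as a fractional shift) is refitted and the
largest objective-function drop above 3.84 (chi-square, 1 df, 5%) enters.
Only forward inclusion is implemented; in the study's analysis no further
covariate reached significance after the body-weight and CRRT relations, so
backward elimination would have nothing to remove. Candidate fits start
from fresh literature values rather than the current estimates: when a
covariate effect is absorbed into an inflated IIV variance, a warm-started
refit reliably lands in that local optimum and the effect is missed.

Two calibration caveats, measured with this package's own experiments and
relevant to interpreting selection results: the null distribution of the
OFV drop is heavier-tailed than chi-square(1) (about 12-16% of null
candidates exceed 3.84 instead of 5% at the study's design, a known
behaviour of approximate-likelihood selection on sparse data), and the
CRRT-on-volume effect is only weakly identified at 152 observations because
steady-state continuous-infusion data carry no volume information. Exact
recovery of the full generating covariate set is therefore unreliable at
this design even though the dominant body-weight-on-clearance relation is
found essentially always.

## Validation

`bootstrap_model()` resamples subjects with replacement, refits each
replicate warm-started from the original estimates (standard practice, and
the original optimum is the natural neighbourhood for a resampled
likelihood), and summarises converged replicates with medians and 95%
percentile intervals. `npde()` implements the standard normalized
prediction-distribution-error construction: the design is simulated
(500 times by default), observed and simulated vectors are decorrelated per
subject with the Cholesky root of the simulation covariance, and ranks are
mapped through the normal quantile function, with draws made per subject in
sorted-ID order so results are invariant to file order. The mean is tested
with a one-sample t-test and the variance with a normal-approximation test;
the simulation uses the same positive-truncated residual multiplier as the
data generator, since that truncation is part of the observation model.
`gof()` produces population predictions, individual (empirical-Bayes)
predictions and conditional weighted residuals from a first-order
conditional linearisation.

## The synthetic cohort generator

The study's clinical dataset is not public, so `generate_cohort()` /
`generate_tdm()` emulate its structure: 45 subjects; body weight with
median 7.88 kg and quartiles 3.62 and 11.97 kg; 38/45 on ECMO and 31/45 on
CRRT; 60% neonates, 9% infants, 31% children; about 152 sparse
concentrations in total (two guaranteed samples per subject plus a Poisson
excess). Dosing follows the protocols: intermittent 20-40 mg/kg 0.5-h
infusions three times daily off ECMO; a 20 mg/kg loading dose (capped at
2 g) followed by continuous infusion (30-80 mg/kg/day under 2 months of
age, 60-120 mg/kg/day above) on ECMO. Specific choices:

* The printed body-weight IQR is asymmetric on the log scale, so no single
  log-normal matches median and both quartiles; weight is drawn from a
  **two-piece log-normal** (different log-SD below and above the median)
  that matches all three exactly in distribution.
* ECMO and CRRT are drawn **independently** at their marginal frequencies.
  Most CRRT subjects are then also on ECMO, as in the cohort, but a few
  intermittently dosed CRRT subjects occur - without them every CRRT
  subject would sit on a steady-state continuous infusion, where
  $C_{ss} = R/CL$ contains no volume information and the CRRT volume shift
  would be unidentifiable in principle.
* CRRT is time-varying within subject: CRRT subjects start on CRRT and a
  single switch-off time is drawn in the later half of the course, so
  datasets contain both on- and off-CRRT observations.
* Sampling times are uniform over the treatment span (the real sampling
  pattern is not reported); the treatment span is 3-7 days per subject.
* Extra covariates (postnatal age by age band, creatinine clearance and a
  mortality score matched to the cohort's medians/IQRs) are independent
  draws with no effect on the PK parameters; they exist to exercise
  covariate selection under the null. Creatinine clearance is drawn
  directly rather than derived from a height-based formula, because heights
  are not part of the data model.
* An optional contamination mode multiplies a fraction of observations by
  3-10, mimicking samples drawn during an ongoing infusion.

What passing the closure tests shows - and what it does not: data generated
from the final model at the study's size and sparsity allow the estimation
machinery to recover clearance-side parameters with little bias (clearance
within a few tenths of a percent, its IIV variance within a few percent over
200 replicates), while volume-side quantities ($V_p$, $\omega^2_V$,
$\theta_{CRRT}$) are recovered with visible small-sample bias, reflecting
how little volume information sparse, largely steady-state data contain.
None of this validates the model against real ECMO patients; circuit
adsorption, time-varying hemofiltration settings and correlated covariates
are all outside the generator.

## Problem sizes used by the test suite

The suite runs the published experiment sizes where feasible: 10,000
simulated subjects per PTA cell, 200 parameter-recovery replicates, a
200-replicate bootstrap (scaled down from the published 1000; the stability
property it measures is insensitive to the extra replicates), 500 NPDE
simulations over 20 calibration runs. The stepwise-selection consistency experiment uses 25 replicate
datasets; with roughly thirty refits per replicate this is the largest size
that keeps the whole suite inside a sensible runtime, and the conclusion it
measures (see the calibration caveats above) is insensitive to doubling it.

## Known limitations

* One-compartment structure only; the published model comparison also
  explored two-compartment variants, but the final model - and everything
  simulated from it - is one-compartment.
* The Laplace approximation biases variance components downward on very
  sparse designs ($\omega^2_V$ especially); quadrature-based estimation
  would reduce this at substantial cost.
* PTA cells for intermittent regimens at mid-range MICs depend on
  unpublished details of the original simulation procedure (grid
  resolution, noise handling); with the fixed hourly-grid convention this
  package reproduces the continuous-infusion cells and the saturated cells
  of the 40% block, while some intermittent mid-range and extreme-MIC cells
  deviate by more than the Monte Carlo error.
* Dose individualisation (TDM feedback dosing) and loading-dose simulation
  for the continuous regimens are out of scope.
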