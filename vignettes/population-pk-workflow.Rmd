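---
title: "Population pharmacokinetics of resveratrol in rats: models, estimation, diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of resveratrol in rats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saempk)
```

`saempk` implements the complete quantitative workflow of a single-dose
preclinical pharmacokinetic study of resveratrol in Wistar rats: structural
two-compartment models for the intravenous and oral routes,
non-compartmental analysis, nonlinear mixed-effects estimation by the
stochastic approximation EM (SAEM) algorithm, simulation-based model
diagnostics, and the ancillary protein-binding, tissue-distribution and
bioanalytical-validation computations. Because no raw animal data are
publicly deposited for this kind of study, the package ships synthetic-data
generators whose defaults reproduce the study conditions: these are
first-class, tested code, and every downstream stage is exercised against
them.

## Structural models

Disposition is mammillary two-compartment. In amount space (amounts in
mg/kg), with first-order rates (1/h),

$$\frac{dA_0}{dt} = -k_a A_0 \;(\text{oral}),\qquad
\frac{dA_1}{dt} = k_a A_0 - (k_{10}+k_{12})A_1 + k_{21}A_2,\qquad
\frac{dA_2}{dt} = k_{12}A_1 - k_{21}A_2,$$

where $k_{10}$ is elimination from the central compartment, $k_{12}$ and
$k_{21}$ are distribution and redistribution, and $k_a$ first-order
absorption. Plasma concentration is $C = 1000\,A_1/V$ (ng/mL, with $V$ in
L/kg — the factor 1000 converting mg/L to ng/mL lives only inside the
concentration functions). The macro (biexponential) rates $\alpha>\beta$
are the roots of $\lambda^2 - (k_{10}+k_{12}+k_{21})\lambda +
k_{10}k_{21} = 0$; `macro_from_micro()` enforces the identities
$\alpha+\beta = k_{10}+k_{12}+k_{21}$ and $\alpha\beta = k_{10}k_{21}$ to
1e-10 relative precision. Closed forms (`conc_iv()`, `conc_oral()`) are
the primary computational route; `conc_ode()` integrates the same system
with `deSolve` and serves as the independent oracle — the test suite
requires 1e-6 relative agreement over the quantifiable range of each
profile.

Two conventions deserve emphasis:

* **Oral volume absorbs bioavailability.** $F$ is not identifiable from a
  single-route fit, so the oral $V$ is the apparent $V/F$ (likewise
  CL/F). Absolute bioavailability is computed only in the NCA module from
  both routes, $F = (AUC_{po}/D_{po})/(AUC_{iv}/D_{iv})$.
* **Degenerate parameter sets are rejected, not patched.** A repeated
  disposition root, or $k_a$ within 1e-8 relative of $\alpha$ or $\beta$,
  raises an error rather than switching to the repeated-root limit form.
  These are probability-zero sets under the generators, and the limit
  forms would complicate every consumer of the model for no statistical
  benefit.

## The statistical model and its generator

Between-subject variability is log-normal per parameter,
$\theta_i = \theta\,e^{\eta_i}$ with $\eta_i \sim N(0, \omega^2)$
(diagonal $\omega$ — no correlations, matching the per-parameter
presentation of preclinical popPK tables), and residual error is
proportional, $Y_{ij} = F_{ij}(1+\varepsilon_{ij})$ with
$\varepsilon_{ij}\sim N(0,b^2)$.

`simulate_population()` draws $\eta$, evaluates the structural model at the
design's nominal times, applies the proportional error, and flags values
below the assay LLOQ (62.5 ng/mL) as censored with DV set to the LLOQ
(NONMEM-style `CENS = 1`). Negative draws — possible under a proportional
Gaussian error — are likewise flagged censored rather than resampled:
resampling would truncate the error distribution the fitter assumes.

The default study conditions are those of the emulated experiment:

| arm | dose | schedule (h) | n | typical values | $\omega$ | $b$ |
|---|---|---|---|---|---|---|
| i.v. bolus | 5 mg/kg | 0.125, 0.25, 0.5, 1, 1.5, 2, 4, 8, 24 | 6 | $V$ 3.60, $k_{10}$ 0.17, $k_{12}$ 1.20, $k_{21}$ 0.26 | 0.3 | 0.22 |
| oral | 100 mg/kg | 0.25, 0.5, 0.75, 1, 1.5, 2, 4, 6, 10, 24 | 6 | $V/F$ 22.20, $k_{10}$ 0.43, $k_{12}$ 4.09, $k_{21}$ 0.44, $k_a$ 1.88 | 0.3 | 0.41 |

The generator's contract takes $\omega$ on the log-SD scale. Published
preclinical BSV figures are often ambiguous in scale between routes; the
presets therefore use $\omega = 0.3$ (about 30% CV) on every parameter — a
typical preclinical magnitude — rather than attempting to reproduce
ambiguous table entries. What the generator deliberately does **not**
emulate: the double concentration peak seen after oral dosing
(enterohepatic recirculation — not part of the fitted structural model),
metabolite kinetics, and inter-occasion variability.

Two further generators cover the ancillary assays.
`simulate_tissue()` drives each organ through a one-rate equilibration
compartment, $dT/dt = k(K_p C_p - T)$, solved in closed form against the
typical biexponential plasma curve; per-tissue defaults (`default_tissue_kp()`)
are illustrative — chosen to produce a qualitatively realistic organ
pattern, including a slowly equilibrating stomach whose concentration
still rises at 11 h — and are not estimates. The destructive design
(three animals per terminal time) is respected: each plasma value comes
from a different simulated animal. `simulate_binding()` emulates the
ultrafiltration assay with a membrane-adsorption fraction and linear
(concentration-independent) binding with default $f_u = 0.21$, i.e. 79%
bound.

## Non-compartmental analysis

`nca_summary()` computes the classic single-dose parameter set. The
numerical choices, where the field's "classic equations" leave latitude:

* **Terminal slope**: log-linear least squares on the suffix of at least
  three points maximizing adjusted $R^2$ (the de-facto standard rule);
  for oral profiles the point at $C_{max}$ and everything before it are
  excluded; near-ties within 1e-4 prefer the longer suffix. A flat or
  rising tail is an error; $R^2_{adj} < 0.5$ sets a warning flag.
* **Trapezoids**: linear-up/log-down by default (plain linear by flag),
  with the matching exact moment formulas for AUMC on log segments.
* **Leading segment**: for i.v., $C(0)$ is back-extrapolated log-linearly
  from the first two samples; for oral the curve rises linearly from 0.
* **Extrapolation**: $AUC_{0-\infty} = AUC_{0-t} + C_{last}/\lambda_z$
  with the observed last quantifiable concentration.
* **Censoring**: BLQ records are dropped; a trailing BLQ simply truncates
  $AUC_{0-t}$ at the last quantifiable sample.
* **Oral MRT** is reported without absorption correction, and oral $V_d$
  as $V_z/F$, making no identifiability claim on $F$.

On dense noise-free model-generated profiles the suite requires NCA to
recover $CL = V k_{10}$ and $\lambda_z = \beta$ within 2% — the NCA engine
doubles as an unbiased oracle for the structural model's exposure.

## SAEM estimation

`saem_fit()` maximizes the exact (non-linearized) mixed-effects likelihood.
Per iteration:

1. **E-step**: adaptive Metropolis on each subject's log-parameters
   $\phi_i$, vectorized across subjects — one independence proposal from
   the current population prior, one full-vector random walk and one
   componentwise sweep per kernel cycle (2 cycles by default), all scales
   adapted toward ~30% acceptance by Robbins–Monro.
2. **SA-step**: exponential-family sufficient statistics updated as
   $S_k = S_{k-1} + \gamma_k(s_k - S_{k-1})$ with $\gamma_k = 1$ during
   burn-in (300 iterations) and $(k - k_{burn})^{-0.7}$ during smoothing
   (200 iterations).
3. **M-step** (closed form): $\mu = $ mean of $\phi$, $\omega^2 = $
   variance, $b^2 = $ mean squared proportional residual. During burn-in
   the variance updates are annealed (bounded below by 95% of the previous
   value) so the random effects cannot collapse before the typical values
   have moved.

BLQ policy: `"drop"` by default; `blq = "m3"` keeps censored records with
a cumulative-normal likelihood contribution in the E-step and the
log-likelihood, and adds the exact truncated-normal conditional
expectation of $\varepsilon^2$ to the $b$ update — an exact EM step for
censored Gaussian errors. M3 matters whenever censoring is informative: at
the i.v. design, a one-compartment profile's typical 24 h concentration is
below the LLOQ, and dropping those records visibly distorts the terminal
phase (this is demonstrated by the likelihood-ratio calibration test).

Initial values are data-driven: a pooled naive fit (log-scale least
squares of the structural model on the geometric-mean profile, run from a
small grid of starting points) seeds the SAEM. Standard errors come from a
linearized Fisher information — finite-difference sensitivities of each
subject's prediction at its conditional mode, giving an explicit Gaussian
marginal whose Hessian is computed by central differences; since $\theta$
is log-parameterized, the SE of $\log\theta$ is directly the relative SE.
The log-likelihood is estimated by importance sampling from Gaussian
proposals centred at the conditional modes with twice the MCMC posterior
covariance (relative ridge, so the proposal stays on the posterior's scale
even when the random effects collapse); its Monte-Carlo SE is reported,
and AIC $= -2LL + 2p$, BIC $= -2LL + p\ln n$ follow. Convergence is
declared when the relative SD of each typical-value trace over the final
20% of iterations is below 5%; a moving trace yields a warning, never a
silent failure.

### Flip-flop ambiguity and how the package treats it

The oral triexponential model has a label-switched likelihood mode in
which $k_a$ exchanges roles with the fast disposition rate. At realistic
residual-error magnitudes the two modes — and a connecting ridge along
which $(V, k_{10}, k_{12}, k_a)$ trade off at nearly constant $CL/F$ —
can differ by only a few log-likelihood units. `saem_fit(n_starts = 2)`
therefore starts once from the pooled naive solution and once from its
label-swap conjugate (same three exponential rates, same AUC, roles
exchanged) and selects by importance-sampling log-likelihood with a large
common-seed sample. `fit_absorption_route()` replicates this over several
SAEM runs, pools all candidates, treats candidates within 3 LL units as
tied, restricts to the mode of the best candidate and reports
per-parameter medians — removing most of the algorithmic placement noise
on the ridge. `saem_fit_ensemble()` offers the same median stabilization
for well-identified routes. A cross-route tie-break (preferring the mode
whose fast disposition rate matches an i.v.-established `alpha_ref`) is
available but off by default: for this compound the reported oral
disposition is itself much faster than the i.v. disposition, so the rule
is not reliable, and pure likelihood selection is the defensible default.

This is also the package's main known limitation: when the residual error
is as large as the oral arm's $b = 0.41$, the oral $V/F$ and $k_a$ are
weakly identified, and any maximum-likelihood estimator — however well
converged — scatters substantially across data realizations. The
parameter-recovery tests document this honestly: the i.v. arm recovers
tightly; the oral arm's recovery depends on the realization.

## Diagnostics

`vpc()` simulates replicate datasets under the fitted model at the
observed design (1000 by default, matching the study's own check; a
smaller count is fine for continuous-integration use and is recorded in
the result's metadata) and compares observed 5th/50th/95th percentiles per
nominal-time bin against the simulation 90% bands. Designs here are
nominal-time, so binning is one bin per unique time; no adaptive binning
is needed. `npde()` decorrelates each subject's observation vector with
the simulated mean and the Cholesky factor of the simulated covariance
(ridge 1e-8), maps componentwise ranks through the standard-normal
quantile (rank fractions clamped away from 0 and 1), and reports mean,
variance and normality tests — under a correct model the NPDE are
approximately iid $N(0,1)$, so mean and variance should be close to 0
and 1. Both are pure functions of (fit, seed). `gof_tables()` emits
observed vs population/individual predictions with proportional-error
weighted residuals.

The calibration tests run these diagnostics under the generating model
(via `population_fit()`, which wraps known parameters in a fit-shaped
object, with linearized conditional covariances as importance-sampling
proposals): NPDE mean within 0.1 and variance within 0.15 of 1 at n = 100
subjects and 500 simulations; VPC median coverage of at least 80% of bins
across seeds; and a mis-specified one-compartment fit must be flagged by
early-time VPC exclusions.

## Ancillary assays and validation statistics

`fraction_unbound()` computes $f_u = C_u/C_t$ with the membrane-bound
amount either recovered additively into $C_u$ (default — the assay
quantifies drug adsorbed to the ultrafiltration membrane precisely so it
can be restored), removed from the denominator, or ignored; rows with
corrected $C_u > C_t$ are flagged and excluded with a warning. Linearity
of binding is an OLS zero-slope test of $f_u$ against total concentration.
`tissue_summary()` reports per-tissue/time means with $K_{p,app}$ from
group means (destructive sampling has no per-animal pairing across
times); missing plasma yields an absent ratio, never zero.

`weighted_calibration()` fits the detector response with weights 1, $1/x$
or $1/x^2$ — $1/x$ being the conventional choice for heteroscedastic
chromatographic responses — and back-calculates each standard through the
inverted line. `qc_report()` and `stability_check()` apply the standard
bioanalytical acceptance windows: CV ≤ 15% and accuracy 85–115%
(20% and 80–120% at the LLOQ), stability 100 ± 15%. All windows are
closed intervals — boundary values pass.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and is deterministic
given it; `run_pipeline()` refuses configurations without one and writes a
JSON manifest (seeds, settings, package version) from which every output
is reproducible. The test suite runs the full parameter-recovery
experiment at n = 100 subjects per route; diagnostic calibrations use
100–200 simulated subjects with 200–500 replicates; the likelihood-ratio
power and type-I suites use 20 seeds of 50 subjects each. These sizes were
chosen so each suite completes in minutes on a single core while keeping
Monte-Carlo error well inside the asserted tolerances.
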