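---
title: "Model and methods behind flupk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind flupk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flupk)
```

## The problem

Fludarabine (administered as the prodrug f-ara-AMP, measured in serum as
f-ara-A) is given with cyclophosphamide on three consecutive days to deplete
lymphocytes before CAR T-cell infusion. Exposure matters: too little
lymphodepletion limits CAR-T expansion, too much adds toxicity, and the drug
is cleared renally in a population with highly variable kidney function.
`flupk` implements a population-pharmacokinetic description of f-ara-A in
this setting end to end: the structural model, the covariate model, cohort
and study simulation, nonlinear mixed-effects estimation, model diagnostics,
and exposure-targeted dose individualization.

## Structural model

Disposition follows a three-compartment mammillary model with zero-order
(30-minute) infusion input into the central compartment and first-order
elimination from it. With amounts $a_1, a_2, a_3$ (mg f-ara-A):

$$
\begin{aligned}
\dot a_1 &= R(t) - (k_{10} + k_{12} + k_{13})\,a_1 + k_{21} a_2 + k_{31} a_3\\
\dot a_2 &= k_{12} a_1 - k_{21} a_2, \qquad
\dot a_3 = k_{13} a_1 - k_{31} a_3
\end{aligned}
$$

with $k_{10} = CL/V_1$, $k_{12} = CLD_2/V_1$, $k_{21} = CLD_2/V_2$,
$k_{13} = CLD_3/V_1$, $k_{31} = CLD_3/V_3$. Serum concentration is
$a_1/V_1$, reported in ng/mL ($1$ mg/L $= 1000$ ng/mL; the conversion lives
in exactly one place, `pk_concentration()`). Units throughout: hours, mg
f-ara-A, litres, L/h.

The system is linear and time-invariant, so it is solved analytically:
the rate matrix is eigendecomposed, the during-infusion and post-infusion
segments are handled piecewise in closed form, and dose events superpose.
When eigenvalues collide within $10^{-8}$ relative (or the eigenvector
matrix is ill-conditioned) the code falls back to an augmented
matrix-exponential formulation, which is exact but slower. `pk_auc()`
integrates the same exponential solution analytically — no quadrature —
and uses the mass-balance identity $AUC(0,\infty) = \text{dose}/CL$ for
infinite horizons. Setting $CLD_3 = 0$ (and/or $CLD_2 = 0$) reduces the
system exactly to its two- (one-) compartment nested forms.

## Covariate model

The final covariate model splits clearance into a non-renal component that
depends on the CAR-T construct and a renal component proportional to
creatinine clearance, with fixed allometric body-weight scaling (exponent
3/4 on clearances, 1 on volumes):

$$
\begin{aligned}
CL &= \left[\theta_{CART} + \theta_{CRCL}\,\frac{CRCL}{96}\right]
      \left(\frac{WGT}{70}\right)^{3/4} e^{\eta_{CL}},\\
V_1 &= \theta_{V1}\,\frac{WGT}{70}\, e^{\eta_{V1}}, \qquad
V_2 = \theta_{V2}\,\frac{WGT}{70}, \qquad
V_3 = \theta_{V3}\,\frac{WGT}{70},\\
CLD_2 &= \theta_{CLD2}\left(\frac{WGT}{70}\right)^{3/4}, \qquad
CLD_3 = \theta_{CLD3}\left(\frac{WGT}{70}\right)^{3/4}.
\end{aligned}
$$

Defaults of `flu_theta()` are the reference estimates
(4.4 / 3.9 L/h non-renal for axi-cel / tisa-cel, 1.7 L/h renal at the
reference CRCL of 96 mL/min, volumes 41.2 / 14.5 / 10.8 L, distribution
clearances 4.8 / 3.6 L/h at 70 kg). At the reference covariates these give
typical clearances of 6.1 L/h (axi-cel) and 5.6 L/h (tisa-cel).

The CRCL entering the model is absolute Cockcroft–Gault creatinine
clearance in mL/min. BSA-normalized eGFR (mL/min/1.73 m²) is carried as a
separate reporting field and is not the model covariate. Whether the
clinical dose-reduction rule used absolute or normalized values is not
fully documented; `renal_adjustment_fraction()` takes absolute mL/min and
this assumption is stated here deliberately. Volumes scale linearly with
weight; an allometric 3/4 exponent on $V_2$/$V_3$ was considered and not
used, matching the reference parameterization.

## Between-subject variability and residual error

$\eta_{CL}$ and $\eta_{V1}$ are jointly normal on the log scale with a full
2×2 covariance block; `flu_ranef()` defaults reproduce CV 29.8% on CL,
34.8% on V1, correlation 0.9, converting CV% to log-variance by
$\omega^2 = \ln(1 + (CV/100)^2)$. Observations are modeled additively on
the natural-log concentration scale,
$\log y = \log f(t) + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ with
$\sigma = 0.29$ log(ng/mL) by default. The reference table labels this
entry "Error [log(ng/mL)] 0.29" without saying SD or variance; it is
interpreted here as the **SD** of the additive log-scale error, the usual
convention for log-transformed-both-sides models. Because the residual
variance is constant on the log scale, the ε–η interaction term of FOCEI
is inert and the Laplace objective used here is the matching approximation.

## Estimation

`fit_population()` maximizes the Laplace-approximate marginal likelihood.
Per subject, an inner damped Newton search (in C++) finds the conditional
mode $\hat\eta_i$ of the joint −2 log density

$$
g_i(\eta) = \sum_j \left[\frac{r_{ij}^2}{\sigma^2} + \log\sigma^2\right]
 + \eta^\top\Omega^{-1}\eta + \log|\Omega|,
$$

and the subject's objective contribution is
$g_i(\hat\eta_i) + \log\left|H_i/2\right|$ with $H_i$ the curvature of
$g_i$ at the mode; $2\pi$ constants are dropped so magnitudes match the
conventional OFV scale and only differences are interpreted. Samples
flagged below the LLOQ or above the ULOQ are excluded (simple-exclusion
handling; a censored-likelihood treatment is out of scope).

The outer problem works on transformed parameters: fixed effects on the
log scale (positivity by construction), $\Omega$ through its log-Cholesky
factor (positive semi-definiteness by construction; the correlation is
derived, never optimized directly), and $\log\sigma$. The optimizer is an
inverse-BFGS quasi-Newton with central-difference gradients, Armijo
backtracking, a per-component step cap of 1 on the transformed scale, and
restarts from jittered starting points (3 by default; ties broken by the
lowest objective). Convergence is declared when an iteration improves the
objective by less than $10^{-3}$ **and** moves no parameter by more than
$10^{-4}$ relative — the stalled-progress criterion used in practice for
population fits. Standard errors, when requested, come from the numerical
Hessian of OFV/2 at the optimum with delta-method transport to the
reporting scale.

The Laplace objective is validated in the test suite against an adaptive
two-dimensional Gauss–Hermite quadrature of the exact marginal likelihood
(agreement within 0.5 points on single-subject problems, typically within
0.01).

## Identifiability: the peripheral split

One property of the reference estimates deserves emphasis. The peripheral
equilibration rates implied by them are
$k_{21} = 4.8/14.5 = 0.331\,h^{-1}$ and
$k_{31} = 3.6/10.8 = 0.333\,h^{-1}$ — essentially equal. When
$k_{21} = k_{31}$ the two peripheral compartments are kinetically
indistinguishable: any split of $V_2 + V_3$ and $CLD_2 + CLD_3$ preserving
the common rate yields the *same* concentration profile, and the
concentration data carry no information about the split itself. Near that
point the marginal likelihood has a flat ridge along the split direction,
and maximum-likelihood estimates of $V_2$, $V_3$, $CLD_2$, $CLD_3$
individually have very large sampling variance: the optimizer stops at
whichever ridge point its path reaches, while the identified combinations
($CL$, $V_1$, $V_2+V_3$, $CLD_2+CLD_3$, the random-effect block, $\sigma$)
are recovered stably. This is why the recovery experiment below grades the
central volume tightly but the peripheral volumes loosely, and why
estimated deep-compartment parameters from sparse designs should be read
as one admissible decomposition, not as separately meaningful constants.
It also means the convergence rule matters: unlimited polishing drifts
along the ridge fitting noise (the expected likelihood gain from ~12 free
parameters), which is the documented reason for the stalled-progress
criterion above.

## The virtual cohort and study design

No patient-level data ship with the package; `generate_cohort()` draws
covariates matching the study population summaries: weight from a
truncated normal on [52, 101] kg whose *post-truncation* mean and SD are
calibrated to 79.6 and 12.9 kg (the underlying parameters are solved from
the analytic truncated-normal moments); age from a scaled Beta(2.6, 1.8)
on [23, 82] years matching the median of 59; sex 59% male and construct
68% axi-cel as independent Bernoullis; eGFR log-normal (right-skewed, as
the published 39–213.9 range around a mean of 90 implies), truncated to
that range, with scale chosen so the absolute Cockcroft–Gault CrCl —
derived through each subject's BSA — has its median anchored near
96 mL/min. Serum creatinine is back-calculated from the Cockcroft–Gault
identity, and heights come from sex-specific normals solely to exercise
BSA-based dosing. Joint covariate structure beyond the Cockcroft–Gault
link is not published and is not invented: marginals are independent,
which is a stated limitation.

`design_spec()` reproduces the limited sampling scheme: three daily doses
at 0/24/48 h (30 mg/m² f-ara-AMP for axi-cel, 25 for tisa-cel, converted
to f-ara-A by 0.78, renally reduced by 25% for eGFR 45–60 and 40% for
30–45 mL/min, with the boundary going to the higher fraction and values
below 30 raising an error because the protocol is silent there); samples
at 1.5, 2 and 24 h after the day-1 and day-3 infusions; an optional 7 h
sample with probability 0.04 (matching its rarity in the study, 7 samples
across 168 administrations); and one pre-CAR-T sample at 119.5 h.
Quantification limits are 1 and 1000 ng/mL; simulated values outside them
are kept but flagged, and exclusion is applied at estimation time, as it
was for the real data. Typical pre-infusion concentrations sit in the low
ng/mL range, so a realistic fraction of BLQ flags arises naturally.
Per-subject random-number substreams are derived from (seed, subject id),
so changing cohort composition does not reshuffle other subjects' data.
What passing tests on these cohorts cannot show: behaviour under real
covariate correlations, assay error that is not log-normal, or dosing
deviations — the generator emulates the design, not the messiness of a
ward.

## Diagnostics

`gof_table()` reports PRED (typical, $\eta = 0$), IPRED (at the
empirical-Bayes $\eta$), IWRES $= (\log DV - \log IPRED)/\sigma$, and
CWRES from a first-order linearization of the subject model around the
EBE — the FOCE-style formulation; the exact linearization point used by
other software varies, so CWRES is covered by a calibration test (mean
within ±0.05, SD within 1 ± 0.1 on model-correct data) rather than a
bit-for-bit comparison. `pcvpc()` simulates replicate datasets preserving
every subject's doses, covariates and sampling times, prediction-corrects
on the linear concentration scale
($pcY = Y \cdot \mathrm{med}(PRED_{bin})/PRED_{subject}$), applies the
same quantification-limit exclusion to simulated values that the observed
data received, and compares observed 2.5/50/97.5 percentiles per bin with
their central 95% simulation intervals. Binning defaults to the nominal
design times (bins under 5 observations merge into their nearest
neighbour); 1000 replicates by default. `covariate_impact_profiles()`
generates $\eta = 0$ profiles over a covariate grid with the dose held
fixed, which reproduces the expected orderings: lighter patients start
higher under fixed dosing, and impaired renal function accumulates drug
with visibly elevated troughs.

## Dose individualization

`dose_recommend()` uses the MAP clearance from the observations collected
so far. Linear kinetics make exposure additive with
$AUC(0,\infty) = \text{dose}/CL$ per dose, so the outstanding exposure to
a cumulative AUC target is split evenly across the remaining doses as
$\text{dose} = CL \times AUC_{share}$. Subjects without usable
observations fall back to typical values, flagged. No default AUC target
ships with the package — the target is a clinical input. In a closed-loop
simulation, MAP-guided dosing after day 1 reduces the spread (CV) of
achieved cumulative AUC relative to fixed BSA dosing.

## Numerical choices and problem sizes

Eigendecomposition tolerance $10^{-8}$ relative for the degenerate
fallback; inner Newton tolerance $10^{-8}$ with ridge damping and step
halving; finite-difference steps $10^{-4}$ (inner Hessian, CWRES
gradients) and $10^{-5}$ (outer gradients); SE Hessian via `numDeriv`.
The recovery experiment in the acceptance script uses 3 replicate
56-subject cohorts under the study design with starting values at the true
fixed effects jittered by 10% log-normal (and variability initialized off
the truth at CV 25/40%, correlation 0.7, σ 0.35), reflecting how a
modeller starts from plausible clinical values; the test suite uses
cohorts of 8–150 subjects depending on what each property needs. The
pcVPC self-consistency test uses 200–300 replicates; the shipped default
for analysis remains 1000.

## Known limitations

Inter-occasion variability is not modeled (explored in the source analysis
but not retained, and no parameters are available). BLQ handling is
exclusion, not a censored likelihood. The 1% LRT threshold is used as
printed (6.61; the exact $\chi^2_1$ value is 6.635). Covariate marginals in
the virtual cohort are independent apart from the Cockcroft–Gault link.
Saturable elimination and intracellular triphosphate kinetics are out of
scope. And as discussed above, individual deep-compartment parameters are
not separately identifiable near the reference estimates — only their
identified combinations should be interpreted.
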