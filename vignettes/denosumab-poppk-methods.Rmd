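---
title: "Methods: population PK of denosumab with parallel linear and saturable elimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of denosumab with parallel linear and saturable elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denopk)
```

## The model

Serum denosumab after subcutaneous (SC) dosing is described by a
one-compartment model with first-order absorption from a depot and two
parallel elimination pathways from the central compartment: a linear
(non-specific, reticuloendothelial) clearance and a saturable
Michaelis–Menten term standing in for target (RANKL)-mediated disposition.
With depot and central amounts $A_d, A_c$ (mg) and $C = A_c / (V/F)$:

$$\frac{dA_d}{dt} = -KA \cdot A_d, \qquad
  \frac{dA_c}{dt} = KA \cdot A_d - \frac{CL}{F} C - \frac{V_m C}{K_m + C}.$$

All parameters are apparent (F-scaled): bioavailability is not separately
identifiable from extravascular data alone, so doses enter the depot at
their full labeled amount and F is absorbed into $CL/F$ and $V/F$.  The
model is deliberately minimal: monoclonal antibodies distribute little
beyond plasma, and without circulating-target (RANKL) measurements a full
target-mediated disposition model is not identifiable, while the
Michaelis–Menten approximation still captures the dose-dependent
non-linearity — at 35 mg the saturable route shapes much of the profile,
while at 120 mg it is nearly saturated and disposition is dose-proportional.

Population structure follows the standard exponential (MU-referenced)
parameterization.  For subject $i$ with body weight $wt_i$ (kg), study
indicator $s_i$ (0 = rich single-dose study in healthy men, 1 = sparse
multiple-dose study in postmenopausal women) and random effects
$\eta_i \sim N(0, \mathrm{diag}(\omega^2_{CL}, \omega^2_V, \omega^2_{KA}))$:

$$CL_i = \exp\!\big(\mu_{CL} + \beta_{bw} \log(wt_i / 70) + \eta_{i,CL}\big),
\quad V_i = \exp\!\big(\mu_V + \beta_{study}\, s_i + \eta_{i,V}\big),
\quad KA_i = \exp\!\big(\mu_{KA} + \eta_{i,KA}\big),$$

with $K_m$ and $V_m$ shared across subjects (no IIV — the data do not
support subject-level variation of a weakly identified saturable pathway).
Body weight is centered at 70 kg, so $\exp(\mu_{CL})$ is the typical
clearance of a 70 kg subject; the power form on CL is the allometric
choice, scaling both size and metabolic rate.  The study coefficient acts
additively on $\log V$ with the rich study as reference level, i.e. the
sparse-study typical volume is $\exp(\mu_V + \beta_{study})$.  Treatment
(biosimilar vs. reference product) can be switched onto CL, V or KA as an
indicator covariate for pairwise arm comparisons; the expectation in a
biosimilarity setting is that these terms do not improve the fit.

Observed concentrations carry proportional residual error,
$y_{ij} = \hat C_{ij} (1 + \varepsilon_{ij})$,
$\varepsilon \sim N(0, \sigma^2)$.

### Units, and the scale of the saturable pathway

Internally everything is mg, L, day; concentrations are mg/L (= µg/mL).
Dataset files store DV in ng/mL, the bioanalytical reporting unit, and the
reader divides by 1000.  The package's published parameter sets hold
$K_m$ in mg/L (0.124 / 0.162) and $V_m$ in mg/day (0.139 / 0.128).  On
this scale the low-concentration limit of the saturable clearance,
$V_m/K_m \approx 1.1$ L/day, dominates the linear 0.12–0.14 L/day
clearance — producing the well-documented accelerated terminal decline of
denosumab — and the simulated 120 mg exposures land on the published
scale (mean AUC$_{0-\infty}$ near $7.5\times 10^5$ ng·day/mL).  Reading
those numerals as ng-scale quantities instead would make the saturable
pathway numerically inert ($V_m/K_m$ unchanged but $V_m$ capped at
0.139 µg/day) and is inconsistent with mg doses and L/day clearances, so
the package treats the ng labels as a unit-label slip and documents the
choice here.  AUC summaries are reported on both scales (mg·day/L and
ng·day/mL) to keep either reading checkable.

## Censoring (BLQ) policy

Below-quantification (BLQ) samples are handled by profile position:
leading BLQ values (before the first measurable concentration) are imputed
as DV = 0 and retained — they carry real information that absorption has
not started delivering measurable drug; trailing BLQ values (after the
last measurable concentration) and BLQ values sandwiched between
measurable ones are removed.  The policy is idempotent and never touches
measurable records.  The assay's LLOQ is configurable (default 20 ng/mL, a
typical electro-chemiluminescence mAb assay scale); only the flagging
depends on it.  Imputed zeros enter the likelihood with an additive
variance floor of $(10^{-6}\ \mathrm{mg/L})^2$, because a proportional
error model gives a zero-prediction record zero variance.  A
likelihood-based censored treatment (the M3 method) is deliberately out of
scope.

## Estimation

The marginal likelihood integrates the conditional density over each
subject's random effects.  The package approximates each subject's
integral by expansion about the conditional mode $\hat\eta_i$ (the
empirical Bayes estimate), with *interaction*: the residual variance
$\sigma^2 \hat C_{ij}(\eta)^2$ is evaluated at the conditional prediction.
The objective is

$$\mathrm{OFV} = \sum_i \Big[ \sum_j \big( \log 2\pi v_{ij} +
  r_{ij}^2 / v_{ij} \big) + \log|\Omega| + \hat\eta_i' \Omega^{-1}
  \hat\eta_i + \log|H_i| \Big],$$

where $H_i$ is the curvature of the joint negative log density at the
mode.  Two forms of $H_i$ are available: the full finite-difference
Hessian (`correction = "laplace"`, the default — the second-order Laplace
form) and the expected (Gauss–Newton) information with interaction
(`correction = "foce"`, the classical FOCE-I form, at roughly half the
ODE solves per evaluation and with analytic outer gradients available;
the replicated recovery checks use it).  At the residual-error levels of
these studies (17–19.5%) the two agree closely; the package's acceptance
suite pins the default objective against 41-node adaptive Gauss–Hermite
quadrature on one-random-effect instances across a 3×3×3 grid spanning
the published estimates, at an absolute tolerance of 0.1.
Two properties of that comparison are worth knowing: the agreement
degrades smoothly as $\sigma$ grows beyond ~0.2 (intrinsic conditional-mode
approximation error, shared by all FOCE-class estimators), and instances
must respect the BLQ policy — keeping sub-LLOQ records under a
proportional error model manufactures multimodal conditional posteriors on
which mode-based methods are not well defined.

The inner (mode) search is a damped Gauss–Newton iteration on the three
etas with a 2-log-unit trust cap per step and an $|\eta| \le 8$ box.  It
runs on exact prediction sensitivities: the ODE system is augmented with
the variational equations for the derivatives of the central amount with
respect to the log-scale parameters, so each iteration costs one (larger)
integration instead of a cluster of finite-difference solves, and the
Jacobian doubles as the material for the expected-information correction.
Modes are warm-started across outer iterations, and a warm start is
discarded whenever the prior mode scores better (stale starts can
otherwise park a subject in a poor local basin of a multimodal
conditional posterior).  Subjects with no informative observations sit at
the prior mode and contribute zero.

The outer problem optimizes typical values and variances on the log scale
and covariate coefficients on the natural scale with `nlminb` (PORT),
inside a generous physiological box that keeps the search out of regimes
where the Michaelis–Menten term makes the system infeasibly stiff.  Outer
gradients come from the envelope theorem at the conditional mode — at the
mode, the derivative of each subject's contribution with respect to a
fixed effect reduces to the data-term partial, assembled from the same
variational sensitivities, with exact expressions for the variance
parameters' $\log|H|$ pieces — except for the absorption and saturable
pathway typical values (KA, $K_m$, $V_m$), whose neglected curvature terms
are not small; those three components are overridden with forward
differences at step $10^{-4}$, far above the solver noise floor.  The
integration tolerances inside the likelihood are kept tight (relative
$10^{-8}$, absolute $10^{-10}$ mg): loosening them to $10^{-7}$ was
observed to let the optimizer stop prematurely on the flattest directions.

The objective has a characteristic curved, badly scaled valley coupling
$CL$, the weight exponent, $K_m$ and $V_m$ (their curvatures span two
orders of magnitude), along which a first optimizer pass routinely stalls
with a "false convergence" report.  The fitter therefore estimates the
diagonal curvature at the stall point by central differences and restarts
the optimizer with the corresponding parameter scaling, repeating (and
re-estimating the scale after large moves) until *restart stationarity*:
the fit counts as converged only when a further scaled restart cannot
improve the OFV by more than 0.1, the resolution relevant to
likelihood-ratio comparison.  This guards symmetrically against premature
stops on the noise floor and against genuinely unfinished runs.

Standard errors come from the inverse observed information (central
finite differences of the OFV at the optimum); natural-scale estimates and
95% CIs use the delta method / interval transformation, with the
log-scale SE reported directly as the natural-scale %RSE.  IIV is reported
as CV% $= 100\,\omega$ (the convention commonly used with exponential
models; note $100\sqrt{e^{\omega^2}-1}$ would differ visibly at the KA
level of ~60%).  Covariate inclusion is tested by likelihood ratio against
$\chi^2$ with one df per added parameter ($\Delta$OFV > 3.84 at
$\alpha = 0.05$); treatment terms are tested pairwise per arm pair.
Shrinkage is $100(1 - SD(\hat\eta)/\omega)$.

## The synthetic-trial generator

The generator's defaults are the two source designs:

* **Rich study** — 255 healthy men, 85 per arm in three arms (biosimilar,
  EU- and US-sourced reference), one 35 mg SC dose, 23 scheduled samples
  from pre-dose through day 253 (hour-scale times stored as 4-decimal
  fractional days), weight truncated-normal 82.97 (SD 8.492) kg on
  [50, 130] kg, study = 0.
* **Sparse study** — 555 postmenopausal women in a 2:1:1 allocation
  (rounded; realized sizes configurable), 60 mg SC at days 0, 183 and 365
  ("month" = 30.4 days, so month 6 = day 183), six scheduled samples (day 1
  pre-dose, day 11, months 1, 3, 6 and 12, the month-6 and month-12 samples
  pre-dose), weight truncated-normal 63.196 (SD 8.787) kg on [40, 110] kg,
  study = 1.

Weights use a truncated normal because only means and SDs are reported;
the bounds are conventional screening limits for the two populations.
Random effects are drawn independently per parameter (diagonal $\Omega$,
matching the reported per-parameter IIV with no correlation terms), DV
values are the true profile times $(1+\varepsilon)$ floored at zero
(flooring rather than redrawing keeps the error distribution simple;
negative draws are rare at $\sigma \approx 0.17$–0.195), BLQ flags are set
where DV < LLOQ, and an optional missing-at-random rate thins scheduled
samples (default 0; about 0.25 reproduces the order of the realized sample
counts in the rich study).  Pre-dose samples at a dose time are evaluated
before the dose (observation rows precede dose rows at tied times, and the
solver records outputs before applying a coincident bolus).

Two consequences of simulating with a proportional error model deserve
emphasis for *recovery* experiments — refitting data the generator itself
produced.  First, the LLOQ omission policy is not applied in between:
deleting below-LLOQ records from self-generated data is informative
censoring that a likelihood without a censored-data term cannot correct
(in a controlled experiment at the full rich design it biased CL by about
−11% and $K_m$ by +51%, while the uncensored loop recovered the
generating values essentially exactly).  Second, the recovery fits raise
the additive variance floor to $(1\ \mathrm{ng/mL})^2$ — a small
combined-error term: simulated troughs of the sparse design fall to
$10^{-5}$ ng/mL, and under a pure proportional error model such
physically unmeasurable records carry unbounded *relative* information
and visibly distort the fit; the floor down-weights them smoothly, with
no selection effect and no change to records in the measurable range.
On real assay data the omission policy (and the resulting caveat) applies
as stated in its own section; the package's parameter sets, like any
estimates produced under record omission, absorb whatever censoring bias
the real assay induced.

What the generator does *not* emulate — and hence what passing recovery
tests cannot show about real data: visit-time jitter (nominal times only,
though jitter is configurable), dropout and enrollment dynamics,
anti-drug-antibody effects on clearance, assay error structure beyond a
single proportional term, correlations between weight and the random
effects, and any pharmacodynamic feedback.

## Derived exposure and model-based bioequivalence

Per-subject $C_{max}$, AUC$_{0-\tau}$ and AUC$_{0-\infty}$ come from the
noiseless individually predicted profile at the empirical Bayes
parameters — model-based metrics, not non-compartmental analysis of noisy
observations.  Profiles are integrated by trapezoid on a dense grid
(≥ 2000 points), the horizon doubling until the terminal concentration
falls below $10^{-4} C_{max}$; the remaining tail is added analytically as
$C(t_{end}) \cdot V / (CL + V_m/K_m)$, the exact low-concentration limit.
$C_{max}$ is refined by re-solving on a fine window around the grid
argmax.  $\tau$ defaults to the first dosing interval for multiple-dose
subjects and to the last scheduled sampling time (253 days) for the
single-dose design, since no interval is defined there.

Bioequivalence uses the parallel-group two-sample analysis on the log
scale: GMR = exp(mean log reference − mean log test) — reference over
test, so the biosimilar arm is the denominator — with a 90% CI from the t
distribution with Welch–Satterthwaite degrees of freedom, passed when both
bounds lie in [80%, 125%].

The 120 mg extrapolation simulates virtual subjects from the pooled
two-study demographics (a 255:555 mixture of the two weight/study
distributions), draws full IIV, and reports the arithmetic mean and SD of
the noiseless individual AUC$_{0-\infty}$ and $C_{max}$, with AUC given in
both mg·day/L and ng·day/mL.

## Diagnostics

`gof_table()` returns PRED (population prediction, $\eta = 0$), IPRE
(individual prediction at the EBEs) and CWRES from the first-order
expansion about the conditional mode
($E[y] \approx c(\hat\eta) - J\hat\eta$,
$V \approx J \Omega J' + \mathrm{diag}(\sigma^2 c(\hat\eta)^2)$,
$\mathrm{CWRES} = V^{-1/2}(y - E[y])$); CWRES is undefined (NA) for
imputed zero records.  `vpc()` simulates the observed design (doses,
times, covariates) with IIV and residual error — 500 replicates by
default — and compares observed 5/50/95th percentiles per time bin with
the medians of the same percentiles across replicates.  Binning is
nominal-time for rich designs (≤ 30 distinct times) and 6 quantile bins
otherwise; observed percentiles exclude imputed-zero records, and for a
like-with-like comparison the simulated values are truncated at the same
LLOQ before their percentiles are computed (a censored dataset only ever
shows the above-LLOQ part of the distribution, so an untruncated band
would sit systematically low in heavily censored bins — heavily enough to
break the VPC's own self-consistency in late bins); bins whose simulated
values fall wholly below the LLOQ in most replicates report an undefined
band.  Stratification by arm or study is available.  Numbers are the
contract; plotting is left to the user's toolkit.

## Problem sizes and seeds in the shipped checks

The test suite exercises recovery at the design sizes the statistics
support on a single CPU in a reasonable sitting: three seeded replicates
of the full 255-subject rich design for the phase-I-style recovery, and
three replicates of a scaled pool (102 rich + 250 sparse subjects) for the
pooled recovery — the sparse arm scaled down from 555 because the study
coefficient's sampling error grows only like $1/\sqrt{n}$ while fit cost
grows linearly.  "Most replicates" criteria are asserted as at least 2 of
3 per parameter.  The acceptance script runs one replicate of each (with
300 sparse subjects in the pool), the 2000-subject extrapolation, and one
null-bioequivalence trial (85 vs 85); the oracle-equivalence grid and
closed-form checks run at full precision.  Every stochastic step takes an
explicit seed; the acceptance script derives all of its sub-seeds from the
single `--seed` argument.

## Known limitations

* One compartment only; profiles of occasional subjects with measurable
  late-time concentrations (beyond ~140 days after 35 mg) are better
  served by a second compartment, which is out of scope.  The
  subject-exclusion option of the fitting stage supports the corresponding
  sensitivity analysis.
* The Michaelis–Menten term approximates target-mediated disposition
  without target dynamics; $K_m$ and $V_m$ are population-level constants.
* FOCE-class objectives deviate from exact quadrature when per-subject
  information is very sparse *and* variances are large; the shipped oracle
  grid quantifies this regime.
* Wald (information-based) CIs only; no bootstrap, no SAEM alternative,
  no full $\Omega$ covariance structure.
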