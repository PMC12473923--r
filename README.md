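# denopk

Population pharmacokinetics (popPK) of subcutaneous denosumab, built for
biosimilarity assessment: a one-compartment model with first-order
absorption and *parallel linear plus saturable (Michaelis–Menten)
elimination*, the covariate structure of a two-study meta-analysis (body
weight on clearance, study on volume, treatment tested on everything), an
approximate marginal-likelihood (Laplace / FOCE-with-interaction)
estimation engine, visual predictive checks, model-based bioequivalence
against the 80–125% margin, and virtual-trial simulation for dose
extrapolation.

The intended users are pharmacometricians and statistical programmers who
want a self-contained, fully testable replica of this analysis type:
every stage runs on synthetic trials that emulate the two source designs
(a rich 255-subject single-dose 35 mg study in healthy men and a sparse
555-subject 60 mg every-6-months study in postmenopausal women), so the
whole pipeline is reproducible without access to any trial data.

## The model

For subject *i* with weight `wt` (kg), study indicator `s` (0 rich / 1
sparse) and log-normal random effects `eta`:

```
dA_d/dt = -KA * A_d
dA_c/dt =  KA * A_d - (CL/F) * C - Vm * C / (Km + C),    C = A_c / (V/F)

CL_i = exp(mu_CL + beta_bw * log(wt/70) + eta_CL)
V_i  = exp(mu_V  + beta_study * s      + eta_V)
KA_i = exp(mu_KA + eta_KA)
y_ij = C_ij * (1 + eps_ij),   eps ~ N(0, sigma^2)
```

Units are mg / L / day (concentrations mg/L = µg/mL; dataset files store
DV in ng/mL).  The saturable pathway stands in for target
(RANKL)-mediated disposition: its low-concentration limit `Vm/Km` (about
1.1 L/day) dominates the 0.12–0.14 L/day linear clearance, giving
denosumab its fast terminal decline at sub-saturating concentrations.
The estimation objective is the conditional-mode (FOCE-I/Laplace)
approximate marginal −2 log-likelihood; see the methods vignette
(`vignettes/denosumab-poppk-methods.Rmd`) for the full account.

## Worked example

Simulate a small rich-design trial from the published phase-I parameter
set, apply the below-quantification policy, and look at the data:

```r
library(denopk)

truth <- denosumab_phase1_model()
truth
#> Population PK model (1-cpt, first-order absorption, linear + MM elimination)
#>   KA 0.406 1/day, V/F 9.33 L, CL/F 0.123 L/day, Km 0.124 mg/L, Vm 0.139 mg/day
#>   covariates: bw_cl = 1.32
#>   IIV CV%: CL 37, V 13, KA 61; proportional residual SD 0.17

sim <- simulate_trial(phase1_design(n_per_arm = 10), truth, seed = 7)
pol <- apply_blq_policy(sim$data)
pol$report
#> BLQ policy report:
#>   leading BLQ imputed to zero : 0
#>   trailing BLQ removed        : 157
#>   intermediate BLQ removed    : 0
```

A single profile and its derived exposure:

```r
p <- individual_params(truth, wt = 83)
prof <- solve_profile(p, dose_events(0, 35), times = c(1, 5, 10, 30, 100, 253))
round(prof$conc, 3)
#> [1] 1.229 3.022 3.119 2.048 0.153 0.000
```

The concentration peaks near day 10 at about 3 mg/L (35 mg into ~9.6 L
with ongoing elimination) and is unquantifiable by day 253.  Model-based
bioequivalence between two arms simulated from identical parameters:

```r
be <- model_based_be(truth, pol$data, test_trt = 1, ref_trt = 2, tau = 253)
be
#> Model-based bioequivalence (reference/test GMR, 90% CI, 80-125% margin)
#>   metric gmr_pct ci_lower_pct ci_upper_pct  pass
#>     cmax  105.71       97.660       114.43  TRUE
#>  auc_tau  112.78       94.085       135.18 FALSE
#>  auc_inf  112.78       94.085       135.18 FALSE
```

With only 10 subjects per arm the CIs are wide (the AUC upper bounds
spill past 125%); at the real design size of 85 per arm the same null
comparison passes in well over 90% of replicates — that operating
characteristic is one of the shipped acceptance checks.  And the 120 mg dose-extrapolation
simulation (pooled two-study demographics, full inter-individual
variability):

```r
extrapolate_dose(denosumab_final_model(), dose = 120, n = 500, seed = 42)
#> Dose extrapolation: single 120 mg SC dose, 500 virtual subjects
#>   AUC0-inf mean 788872 (SD 289026) ng*day/mL  [= 788.9 (289.0) mg*day/L]
#>   Cmax mean 16.16 (SD 4.42) mg/L
```

The mean AUC lands on the published ~7.5e5 ng·day/mL scale with a ~38%
coefficient of variation driven by clearance IIV and body weight.

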