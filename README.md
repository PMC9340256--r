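# escipk — population pharmacokinetics of escitalopram

`escipk` is an R package for analysing sparse therapeutic drug
monitoring (TDM) data for escitalopram in psychiatric patients, and for
turning the fitted model into dosing guidance. It is aimed at
pharmacometricians and clinical-pharmacology researchers who want a
self-contained, tested implementation of the full analysis chain:

* a **one-compartment oral model** with first-order absorption and
  elimination in apparent parameters (CL/F, V/F, fixed ka), with
  log-normal between-subject variability and proportional residual
  error:
  `C(t) = (1000 D / V) · ka/(ka−ke) · (e^(−ke·t) − e^(−ka·t))`,
  `ke = CL/V`, `Pi = TV · exp(ηi)`, `Y = F·(1+ε)`;
* **covariate effects on clearance**: CYP2C19 metabolizer phenotype
  (EM reference, multipliers θ_IM and θ_PM derived from *1/*2/*3
  diplotypes) and age via `1 − θ_Age·(age − 45)`;
* a **FOCE-I estimation engine** (first-order conditional estimation
  with η–ε interaction; Laplace-type objective with Gauss–Newton
  information, compiled inner search, exact objective on
  linear-Gaussian models);
* **stepwise covariate selection** with the likelihood-ratio
  thresholds ΔOFV > 6.63 (forward, p < 0.01) and ≥ 10.83 (backward,
  p < 0.001) and an auditable search log;
* a **validation battery**: nonparametric subject bootstrap,
  conditional weighted residuals (CWRES), normalized prediction
  distribution errors (NPDE) with t/variance/Shapiro–Wilk tests and a
  Bonferroni global p;
* **steady-state dosing simulation** against the AGNP therapeutic
  window (trough 15–80 ng/ml, laboratory alert 160 ng/ml) across
  doses, ages and phenotypes;
* a **synthetic-cohort generator** reproducing the design of a
  106-patient monitoring study (≈337 trough-dominated samples, doses
  5–30 mg/day, ages 12–83, EM/IM/PM ≈ 44/46/9%), used by all
  stochastic tests.

The default parameter values throughout are the final-model estimates
for Chinese psychiatric inpatients: CL/F 16.3 L/h, V/F 815 L, ka
0.6 h⁻¹ (fixed), θ_Age 0.0077/y, θ_IM 0.847, θ_PM 0.479, ω²(CL) 0.0877,
ω²(V) 0.235, proportional error variance 0.0287.

## Worked example

Simulate a virtual monitoring study at the reference estimates, refit
it, and evaluate dosing:

```r
library(escipk)

cohort  <- generate_cohort(cohort_config(), seed = 1)
dataset <- simulate_pkdata(cohort, truth = pk_params(), seed = 1001)
fit     <- pkfit(dataset)               # FOCE-I, ka fixed at 0.6
coef(fit)[c("tvcl", "tvv", "theta_im", "theta_pm", "sigma2_prop")]
#>       tvcl        tvv   theta_im   theta_pm sigma2_prop
#> 16.5331480 848.2289858  0.7906202  0.4592079   0.0305772
```

The recovered typical clearance (16.5 L/h), volume (848 L) and error
variance (0.031) sit close to the generating values 16.3 / 815 /
0.0287 — the estimator reproduces the published analysis on data with
that analysis's own design. Dosing implications by age and phenotype:

```r
trough_table(pk_params(), regimens = lapply(c(10, 20), regimen),
             ages = c(45, 65), n_subjects = 2000, seed = 1)
#>     regimen age phenotype typical_trough    p5   p95 frac_window frac_high
#> 1  10 mg qd  45        EM           20.6  9.94  36.3       0.759    0.0005
#> 3  10 mg qd  45        PM           48.2 27.17  80.6       0.947    0.0530
#> 9  20 mg qd  45        PM           96.5 53.29 164.7       0.326    0.6140
#> 12 20 mg qd  65        PM          115.9 66.72 193.0       0.146    0.6970
```

A typical adult poor metabolizer on 20 mg/day has a steady-state trough
of ~96 ng/ml — above the 80 ng/ml upper bound, with 61% of simulated
patients in the 80–160 band — while 10 mg/day keeps EM/IM/PM adults
inside the window; elderly PM patients exceed the window already at
moderate doses. This is the quantitative basis for capping PM dosing at
10 mg/day and for caution in elderly patients.

The same pipeline is scriptable through a YAML-configured runner
(`run_task("generate" | "fit" | "select" | "bootstrap" | "npde" |
"gof" | "simulate", pk_config(...))`), each task writing result files
and a run log.

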