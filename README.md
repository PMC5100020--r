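# rmphase

Estimating S-phase duration from pulse-chase flow cytometry via the
relative-movement statistic and segmented regression.

## The problem

How long does a proliferating cell population take to replicate its
genome? A brief pulse of a thymidine analog (EdU) labels every nucleus in
S phase; after a chase with excess unlabeled precursor, bivariate flow
cytometry (DNA stain x label) shows the labeled cohort as an arc between
the unlabeled G1 (2C) and G2/M (4C) clusters. As the cohort finishes
replication its mean DNA content converges on 4C. The **relative
movement**

    RM = (F_L - F_G1) / (F_G2/M - F_G1)

normalizes the cohort's mean DNA-stain fluorescence `F_L` between the
unlabeled G1 and G2/M means. Under uniform-cohort, constant-rate theory
RM is 0.5 immediately after the pulse and approaches 1.0 as replication
completes. Fitting RM versus chase time with a **two-line segmented
regression** (one breakpoint `psi`) gives two duration estimates:

* **lower** — the breakpoint itself, where the main cohort finishes;
* **upper** — the first segment `y = b0 + b1 t` extrapolated to RM = 1,
  i.e. `(1 - b0) / b1`, accounting for slower nuclei.

The RM value at the breakpoint (`b0 + b1 psi`) diagnoses subpopulations
that stall mid-S or divide and re-replicate, which keep the plateau
below 1.

The package implements the full pipeline — reading event data (CSV or
minimal FCS 3.1), automated gating with exclusion of returned-to-G1 and
residually labeled nuclei, RM series assembly across replicates, a
from-scratch segmented fit with slope confidence intervals and a
calibrated slope-change (Davies-type) test, and the duration estimates —
plus a stochastic cell-population simulator with known ground truth for
validation.

## Worked example

Simulate a root-meristem-like chase (true S phase 2.7 h, three
replicates, division with G1 return, a slow subpopulation, residual
labeling, debris and measurement noise), then estimate the duration:

```r
library(rmphase)

cfg    <- sim_config(n_replicates = 3L, seed = 20260901L)  # t_s = 2.7 h
tc     <- simulate_time_course(cfg)
series <- assemble_series(tc)      # auto-gates each replicate at 0 h
fit    <- fit_segmented(series)
fit
#> <segmented_fit> y = 0.5987 + 0.1505 t  (t < 2.475 h), slope -0.0517 after
#>   slope1 95% CI [0.1273, 0.1738]; slope2 95% CI [-0.0621, -0.0413]
#>   R^2 = 0.946, RSS = 0.01489, Davies p = 0.001, n = 24

estimate_duration(fit)
#> <duration_estimate> S-phase duration 2.5 h (breakpoint) / 2.7 h
#>  (extrapolated); RM at breakpoint 0.97
```

The fitted breakpoint (2.5 h) tracks the true 2.7 h S phase; the
extrapolated estimate is the upper bound for the slower tail, and the
plateau RM of 0.97 reflects the simulated slow subpopulation. The same
steps run from files via `run_pipeline("manifest.yaml", out_dir = "out")`,
which writes a JSON report, the RM series as TSV and an annotated RM
plot.

The `analysis/` directory holds the package's own study as numbered
drivers: `01_simulate.R` (synthetic courses with known truth),
`02_gate_rm.R` (gates and RM series), `03_fit_duration.R` (fits and
estimates), `04_worked_examples.R` (published first-segment lines worked
through `estimate_duration()`), `05_recovery_study.R` (breakpoint
recovery and the arrest contrast). Each writes its tables under
`results/`.

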