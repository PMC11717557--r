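# scrubbias

Motion quality control in resting-state fMRI excludes participants whose
scans carry too much head motion — but motion tracks who participants are.
In pediatric cohorts, body mass, age, socioeconomic context, cognition, and
psychopathology all predict motion, so listwise exclusion is missingness
*not at random*: every QC pathway reshapes the analyzed sample and biases
analyses of exactly those covariates. `scrubbias` is a toolkit for auditing
that bias, for researchers designing QC pipelines on large developmental
rs-fMRI studies.

It implements the full chain:

- **Framewise displacement** from six rigid-body parameters:
  FD_t = Σ|Δtrans| + r·Σ|Δrot| (arc length at r = 50 mm), with zero-phase
  band-stop filtering of respiratory artifact (0.31–0.43 Hz) before
  differencing.
- **Frame censoring** at thresholds 0.5/0.4/0.3/0.2/0.1 mm, removing frames
  with FD > threshold plus surviving islands of ≤ 5 contiguous kept frames,
  and the 5-minute (375-frame at TR = 0.8 s) minimum-retained-data
  inclusion rule.
- **Eight inclusion conditions** (tabulated `T`, community pre-processing
  `C`, five scrubbing thresholds, recommended `R`) assembled into a
  subjects × conditions exclusion table with counts and overlaps.
- **Exclusion bias models**: bivariate and single-step adjusted logistic
  regressions of exclusion on 17 participant covariates, odds ratios with
  90% Wald (or profile) intervals, Bonferroni families for neighborhood and
  cognitive predictors; FD–covariate correlation and contrast tables.
- **Excess-missingness trajectories**: each subgroup's exclusion rate minus
  the sample's, traced across conditions, exactly zero at the 0% and 100%
  endpoints.
- **QC-FC distance dependence**: per-edge correlations between mean FD and
  connectivity, regressed on inter-ROI Euclidean distance (99% CI) —
  the residual-motion-artifact diagnostic.
- **A synthetic cohort generator** with a Gaussian-copula covariate model,
  a covariate-graded latent motion propensity, AR(1) + respiratory + spike
  motion traces, and a distance-decaying motion-locked connectivity
  artifact, so the whole audit is testable without access-controlled data.

## Worked example

```r
library(scrubbias)

cfg    <- cohort_config(n_subjects = 300, seed = 7)
cohort <- simulate_cohort(cfg)
audit  <- qc_audit(cohort)
audit
#> rs-fMRI QC exclusion-bias audit
#>   300 subjects, seed 7, config 2c5453e5
#>   exclusion by condition:
#>     T       14 (4.7%)
#>     C       58 (19.3%)
#>     0.5     58 (19.3%)
#>     0.4     59 (19.7%)
#>     0.3     65 (21.7%)
#>     R       55 (18.3%)
#>     0.2     78 (26.0%)
#>     0.1    162 (54.0%)
#>   bivariate models: 83 of 248 terms associated with exclusion (alpha = 0.10)
#>   QC-FC distance slope (scrub none): 3.68e-05 [-8.96e-05, 1.63e-04] (99% CI)
#>   QC-FC distance slope (scrub 0.2): 9.55e-05 [-2.78e-04, 4.69e-04] (99% CI)
```

The exclusion ladder shows the two regimes: a fifth of the cohort is lost
before any motion thresholding (condition `C`), scrubbing from 0.5 to
0.2 mm adds a few percent per step, and 0.1 mm excludes over half the
sample. Who is lost is not random:

```r
subset(audit$bivariate_or, condition == "0.2" &
                           covariate %in% c("coi", "age", "bmi_z"))
#>      covariate  term condition odds_ratio    ci_low   ci_high ci_level
#> 2109       coi   coi       0.2  0.4929540 0.3899824 0.6231145      0.9
#> 2117       age   age       0.2  0.8776288 0.7166817 1.0747204      0.9
#> 2118     bmi_z bmi_z       0.2  1.4340365 1.1505479 1.7873751      0.9
```

Under scrubbing at 0.2 mm, a one-SD higher standardized BMI raises the
odds of exclusion by ~43% and a one-SD higher child-opportunity score
halves them, while this cohort's age effect is not distinguishable from
null at this sample size — the audit's core product, per covariate and per
condition. `plot(audit, "trajectory")` draws the excess-missingness
trajectories; `audit$qcfc` holds the QC-FC distance summaries, here flat
(the simulated artifact strength was zero, and the 99% CIs cover 0).
`qc_audit(..., output_dir = "out")` writes all table analogs as CSV plus a
JSON run summary with the seed and config hash; `run_audit("run.yaml")`
does the same from a serialized configuration.

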