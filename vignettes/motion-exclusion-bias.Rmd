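---
title: "Auditing exclusion bias in rs-fMRI motion quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing exclusion bias in rs-fMRI motion quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Resting-state functional connectivity is exquisitely sensitive to head
motion, so standard practice censors high-motion frames ("scrubbing") and
excludes participants left with too little data. But motion is not random:
in pediatric cohorts it correlates with age, body mass, socioeconomic
context, cognition, and psychopathology. Exclusion is therefore missingness
*not at random*: every quality-control (QC) pathway reshapes the analyzed
sample, and analyses of the very covariates that predict motion are
systematically biased by listwise deletion. `scrubbias` implements the audit
of that bias end to end — from raw rigid-body motion parameters to
odds-ratio tables, excess-missingness trajectories, and QC-FC
distance-dependence diagnostics — together with a synthetic cohort generator
so the full chain is testable without access-controlled data.

## The QC pipeline

**Framewise displacement.** For six rigid-body realignment parameters
(translations in mm, rotations in radians), FD at frame $t$ is the sum of
absolute backward differences, rotations converted to arc length on a
sphere of radius $r$ (default 50 mm):

$$\mathrm{FD}_t = \sum_{j\in\text{trans}} |\Delta p_{jt}| +
  r \sum_{j\in\text{rot}} |\Delta p_{jt}|.$$

The first frame has no predecessor; we set $\mathrm{FD}_1 = 0$ rather than
dropping the frame, so FD vectors stay aligned with censoring masks.

**Respiratory filtering.** Fast-TR multiband acquisitions alias chest
motion into the realignment parameters, inflating FD with a factitious
oscillation near the respiratory rate. `filter_respiratory()` applies an
order-2 Butterworth band-stop (default stopband 0.31–0.43 Hz), run forwards
and backwards (`filtfilt`) for zero phase, to each parameter series before
differencing; a `filter_target = "fd_series"` switch filters the FD series
itself instead, for the literal reading of "filtered from FD". Series are
demeaned before filtering and the mean restored, so the DC level is
preserved exactly. The first and last ~10 frames carry edge transients.
Because the filter has finite transition bands, a second pass still changes
a motion-like series by roughly 2–3% RMS; the test suite checks this
near-idempotence at a 5% bound.

**Censoring.** Two passes: (1) censor frames with FD strictly above the
threshold (a frame exactly at the threshold is kept — the rule is
"exceeding"); (2) censor every maximal run of still-kept frames of length
at most `min_island` (default 5) between censored frames. Runs touching the
start or end of a run are treated as flanked and censored by default
(`censor_boundary_islands = TRUE`); the permissive convention is a switch,
since consortium pipelines do not document their choice. Runs are censored
independently; no cross-run difference contributes to FD.

**Inclusion.** A participant is excluded in a motion condition when fewer
than `min_retained_frames` frames survive across runs. The default 375 is
exactly five minutes at TR = 0.8 s (`min_frames_for_minutes(5, 0.8)`); the
boundary is strict, so 375 retained frames is included and 374 is not.

**The eight conditions.** `assemble_conditions()` builds the subjects ×
conditions exclusion table: `T` (tabulated-release visual-inspection
failure), `C` (community-collection pre-motion processing failure), the
five scrubbing conditions 0.5–0.1 mm (each `C` ∪ the motion rule at that
threshold), and `R` (recommended-inclusion: segmentation failure and/or
fewer than 375 frames with FD ≤ 0.2 mm). Scrubbing conditions are nested by
construction: anything excluded at 0.5 mm is excluded at 0.4 mm, and so on.

## The bias models

- `correlate_fd_continuous()` — Pearson correlations of each continuous
  covariate with subjects' mean FD, within each condition's retained
  sample; p-values from the corresponding bivariate linear model.
- `contrast_fd_categorical()` — linear models of standardized mean FD on
  each categorical covariate against the study reference levels, with
  per-level standardized coefficients and the omnibus F-test.
- `fit_bivariate_exclusion()` — one logistic model of exclusion per
  covariate per condition (17 covariates × 8 conditions = 136 models under
  the defaults).
- `fit_adjusted_exclusion()` — one model per condition with all covariates
  entered in a single step, optionally adding site and scanner.
- `apply_bonferroni()` — family-wise correction for the two declared
  families: neighborhood context (ADI, COI) and general cognitive ability
  (matrix reasoning, toolbox total, toolbox crystallized). No other
  correction is applied.

Odds ratios are exponentiated coefficients with Wald intervals at the 90%
level by default (the level the tables of this literature print);
profile-likelihood intervals are available via `method = "profile"`. Wald
p-values and intervals share one variance estimate, so `p < 0.10` and "the
90% CI excludes 1" agree exactly. Complete cases are used per model;
covariate missingness is reported separately (`covariate_missingness()`),
not imputed — remedies such as multiple imputation are out of scope here.
Complete separation is flagged (`flag = "separation"`) with estimates
withheld rather than silently reported; rank-deficient adjusted designs
raise an error naming the aliased terms.

Two analysis choices are deliberately exposed as switches because the
source literature leaves them ambiguous: whether FD–covariate tables use
all subjects or each condition's included subjects (`sample =`, default
included), and whether downstream mean FD is filtered (default) or raw.

**Excess missingness.** For a subgroup $g$ and condition $c$,
$\mathrm{excess}_{gc} = 100\,(\Pr[\text{excl}\mid g, c] -
\Pr[\text{excl}\mid c])$ percentage points, plotted against the overall
percentage excluded. At the endpoints — nobody or everybody excluded — the
excess is identically zero, which the implementation reproduces exactly.
Continuous subgroups default to a ±1.5 SD cut.

## QC-FC distance dependence

For each ROI pair, QC-FC is the correlation across subjects between mean FD
and that edge's connectivity. Connectivity is Pearson correlation over
retained frames, entered as Fisher z by default (|r| clipped at
$1 - 10^{-7}$); the r-scale is a switch, since the source convention is
unstated. Mean FD here is the subject's mean over *all* frames
(pre-censoring, filtered by default), with a retained-frames option. The
diagnostic is the OLS slope of QC-FC on inter-ROI Euclidean distance with a
99% interval; equal-count distance-bin medians are computed for plotting
only — the slope is always fit on raw edges. Zero-variance edges are
flagged and enumerated, never silently dropped.

## The synthetic cohort generator

The generator (`simulate_cohort()`) emulates the *structure* the audit
assumes, not any real sample:

- **Covariates.** Seventeen covariates (6 categorical, 11 continuous
  standardized) tied together by a single-factor Gaussian copula
  ("compound disadvantage") with configurable loadings; categorical
  variables are cut from their latents at the quantiles of configurable
  marginal frequencies. The three psychopathology factor scores load zero
  and are mutually orthogonal by construction. Site and scanner are
  categorical, with optional site intercepts on pre-motion QC failure and
  optional site-graded covariate shifts to create site confounding.
  The copula loadings are plausibility choices, not estimates of any
  cohort — covariate intercorrelations of the motivating study are not
  public.
- **Motion.** A latent propensity $\lambda_i$ is a linear function of the
  latent covariate scores plus noise (`propensity_sd`). Each run combines
  AR(1) baseline noise on all six parameters, a respiratory sinusoid
  (default 0.35 Hz) on two translations, and per-frame spikes with
  probability $\mathrm{logit}^{-1}(\mathrm{logit}(p_0) + \lambda_i)$ and
  shifted-exponential magnitude, so all five thresholds are exceeded at
  graded rates. A per-subject lognormal multiplier on the baseline noise
  level (`baseline_scale_sd`) captures covariate-independent differences
  in continuous motion; without it the strictest threshold behaves like a
  knife edge on the shared noise level, which no real cohort shows.
- **Pre-motion pathways.** Pre-processing failure is logistic with
  configurable covariate and site effects; the visual-inspection (`T`) and
  segmentation (`R`) failure flags are independent low-rate Bernoulli
  draws — declared abstractions, since no operational definition of those
  QC steps is public.
- **Connectivity.** ROI centroids are uniform in a 70 mm sphere. Signals
  are latent-network structure plus noise plus a motion-locked artifact
  whose contribution to an edge's covariance is
  $(\beta_0 + \delta\,\overline{\mathrm{FD}}_i)\,
  e^{-d_{ab}/\lambda_d}$, implemented by spatially-correlated loadings
  (exponential kernel, Cholesky factor) on artifact components whose
  frame-wise amplitude follows the FD trace — so frame censoring removes
  the artifact-carrying frames. Positive $\delta$ yields motion-inflated
  short-range coupling (negative QC-FC distance slope); negative $\delta$
  with a positive base yields motion-suppressed short-range coupling
  (positive slope).

**Default calibration.** The defaults are fixed to reproduce the attrition
profile characteristic of large pediatric multi-site rs-fMRI studies: about
a fifth of the sample lost before motion correction, a few additional
percent per scrubbing step from 0.5 to 0.2 mm (roughly 30% cumulative), and
a majority lost at 0.1 mm, with a low single-digit tabulated-failure rate.
These rates are design targets of the generator, chosen once; the package's
tests then check the *mechanisms* (nesting, recovery, trajectories) on
cohorts drawn under them.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: scanner-specific artifact spectra,
non-stationary or autocorrelated spike bursts, distance-dependent artifact
that is not exponential in Euclidean distance, covariate missingness
mechanisms, true site recruitment differences, and any real operational
meaning of "failed visual inspection". Conclusions about a real cohort
require the audit to be run on that cohort's own motion and covariate
files, which the readers (`read_motion_tsv()`, `read_covariates_csv()`,
`read_centroids_tsv()`) accept directly.

## Numerical choices

- FD's first frame is 0; ties at the threshold are kept.
- Filter: order-2 Butterworth band-stop, zero-phase, demeaned; stopband
  validated against Nyquist with an explicit error.
- Connectivity needs at least 3 retained frames (configurable); Fisher z
  clips |r| at $1-10^{-7}$.
- QC-FC with a flat edge field returns a slope of exactly zero.
- Wald intervals by default; profile intervals optional. Separation flagged
  via non-convergence or extreme coefficient/SE magnitudes.
- Determinism: a cohort is a pure function of (config, seed, components);
  the audit records a config hash and seed in every output.

## Problem sizes

The test suite exercises the censoring oracle on 1000 random series,
parameter recovery at odds ratios 1.2/1.5/2.0 with 4000 subjects over 50
replicate cohorts, trajectory shape on a 1600-subject cohort, and QC-FC
behaviour at 500 subjects × 60 ROIs over 50 replicates;
`scripts/acceptance.R` recomputes the same quantities at moderately
smaller replicate counts. These sizes are the package's own choices of
scale for stable Monte-Carlo checks.

## Limitations

The audit quantifies *who is excluded*, not how exclusion changes
downstream effect estimates; it performs no imputation or weighting. The
generator's copula is single-factor — real covariate dependence is richer.
QC-FC is a marginal diagnostic: a flat slope does not prove the absence of
motion artifact, only the absence of distance-patterned artifact linearly
related to mean FD.
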