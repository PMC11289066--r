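---
title: "Analyzing webcam eye-tracking with AOI bias correction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing webcam eye-tracking with AOI bias correction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

gazekit analyzes screen-based eye-tracking experiments whose outcome is a
viewing proportion over a small number of large areas of interest (AOIs).
It was built for webcam-based gaze estimation (WebGazer-style), whose samples
arrive at roughly 30 Hz with irregular spacing, carry per-sample noise of
tens of pixels, and — most importantly — a spatial offset of the order of
100–150 px that is roughly constant within a trial but drifts between trials
and participants. The package implements the post-hoc correction for that
offset, the participant/trial/sample exclusion cascade typically
preregistered with it, the outcome computation for three classic paradigms
(gaze cascade, novelty preference, visual world), and the inferential layer
used to test them. A synthetic-data generator with known ground truth makes
every stage testable without collecting data.

## The measurement model and the bias correction

A gaze sample is modeled as

$$ (x, y) = (x^\ast, y^\ast) + (\beta_x, \beta_y) + \varepsilon, $$

where $(x^\ast, y^\ast)$ is the true looking position, $\beta$ is the
per-trial measurement bias and $\varepsilon$ is isotropic Gaussian sample
noise. Because each trial opens with a central fixation cross, $\beta$ can be
estimated per trial: `estimate_trial_bias()` keeps the samples in the tailing
80% of the fixation window and takes their mean minus the fixation point.
Two conventions here are deliberate:

* **"Tailing 80%" is defined by time** (`t >= 0.2 * fixation_duration`), not
  by sample count. Webcam sampling is irregular; a time-based window is
  invariant to the realized sample times, while a count-based one is not.
* The **bias statistic is the arithmetic mean** of the kept samples. A median
  is available (`stat = "median"`) for heavy-tailed contamination, but the
  mean is the default because the generator's noise model (and, in our
  experience, webcam noise within a fixation) is roughly symmetric.

`correct_geometry()` then *adds the estimated bias to the geometry*: the
midline(s) and every AOI bound move by $(\hat\beta_x, \hat\beta_y)$; gaze
samples are never modified. The two views are provably equivalent
(`assign_aoi(s, shifted geometry)` equals
`assign_aoi(s - bias, original geometry)`, and the test suite asserts this),
but shifting geometry keeps raw data immutable and auditable. Two-AOI
left/right designs correct the horizontal axis only (`axes = "x"`); the
four-quadrant visual-world design corrects both axes (`axes = "xy"`).

AOI rectangles are half-open, $[x_{\min}, x_{\max}) \times
[y_{\min}, y_{\max})$, with the origin at the top-left corner and y growing
downward. Half-openness makes assignment deterministic when AOIs share a
boundary after correction.

Per-participant data quality can be summarized by `calibration_score()`: the
fraction of samples inside a central region during a post-calibration
fixation. The region is a convention, not a measurement; the default is a
square of 200 px half-width around the screen center and is configurable
because no standard definition exists.

## The exclusion cascade

`apply_exclusions()` applies three levels in fixed precedence —
participants, then trials, then samples — and reports the first rule each
excluded entity triggers, with stage-by-stage retention counts.

Participant rules: exactly zero variance in estimated gaze (the webcam
failure mode is a frozen estimate, hence *exact* zero rather than a small
threshold); zero response variation (response paradigms); more than 50% of
stimulus-phase samples outside all AOIs; more than 50% of trials without
data. All "more than" thresholds are strict, so boundary cases are retained.
Off-AOI fractions are computed over *stimulus-phase* samples: fixation-phase
gaze is at the screen center, outside every AOI by design, and counting it
would mechanically push every participant over the 50% rule.

Trial rules: missing bias estimate; corrected midline farther than 25% of
screen width from the true midline (two-AOI mode); in four-AOI mode each
midline has its own limit — 25% of screen *height* for the vertical position,
37.5% of screen *width* for the horizontal — and exceeding either flags the
trial (a conjunction would essentially never fire, and a trial whose
correction is implausible on one axis is already untrustworthy); fixation
dispersion `sd_x` above 25% of screen width; response time outside
[0.5 s, 30 s]. `sd_x` is the within-trial SD of the tail-window fixation
samples; the across-trial SD of corrected midlines per participant is a
plausible alternative reading and can be computed from the `$biases` table,
but the within-trial SD is the default because it is defined for every trial
independently.

Sample rules: outside all corrected AOIs; optionally flagged by the live
webcam feed (estimator lost the eyes). Whether sample filtering runs before
or after trial flags is not observable in the outcome (the operations
commute); the implemented order is bias estimation, then trial flags, then
the sample filter.

Sensitivity filters (`sensitivity_filter()`) add participant-level checks
cumulatively, in hierarchical order: more than one failed attention check,
instruction screen clicked through in under 7.5 s, self-reported "unreliable"
data, and live-feed sample dropping. Cumulative application guarantees order
stability: no entity excluded at one level is retained at a later level.

## Paradigm outcomes

All three outcomes are viewing proportions whose **denominator is the
in-AOI sample count of the analysis window**. Off-AOI samples are excluded
by the preregistered sample filter before analysis, so including them in the
denominator would conflate data quality with preference; this choice is
stated prominently because proportion denominators are a common source of
silent disagreement between analyses.

* **Cascade**: proportion of window samples on the eventually chosen AOI in
  the 100 ms before the response; the window is right-open, so the response
  moment itself is excluded.
* **Novelty**: proportion of test-phase samples on the novel AOI.
* **Visual world**: proportions per AOI role (target, three distractors) in
  a 400-ms window; within a trial the role proportions sum to 1. The window
  opens 200 ms after target-word onset — a saccade-programming latency — and
  both placement and length are configurable because they are analysis
  conventions rather than measured quantities.

Participant summaries are **unweighted means of trial proportions**: each
retained trial counts equally regardless of how many samples its window
captured, which is the convention in the preferential-looking literature and
keeps long trials from dominating. Time-courses
(`decision_locked_timecourse()`, `stimulus_locked_timecourse()`) average
trials within participants first, then participants, and report the
across-participant SEM per bin.

The paired online/lab comparison (`compare_conditions()`) runs a one-sided
paired t test (lab greater) and decomposes the effect-size difference into
the ratio of Cohen's-d numerators (condition mean minus chance) and the
ratio of across-participant SDs. Degenerate difference vectors are handled
explicitly: identical conditions give t = 0 and unit ratios, a constant
shift gives an infinite t in the shift's direction; neither returns a Bayes
factor.

## Inferential layer

`one_sample_t()` / `paired_t()` wrap the classical test and add three
quantities:

* **Cohen's d** with a one-sided 95% lower confidence bound from the
  noncentral-t inversion: the bound $\delta_L$ solves
  $F_{t,\nu,\;\delta_L\sqrt{n}}(t_{\mathrm{obs}}) = 0.95$, reported as
  $[\delta_L, \infty)$. A Monte-Carlo experiment in the test suite confirms
  ~95% one-sided coverage.
* **JZS Bayes factor** (`jzs_bf()`): the marginal likelihood of the observed
  t under a Cauchy prior (default scale 0.707) on the standardized effect,
  divided by the central-t density — computed by adaptive quadrature of the
  noncentral-t density against the Cauchy. One-sided variants use the
  half-Cauchy on the alternative's side, so the two-sided value is the equal
  mixture of the two one-sided ones (asserted numerically, along with
  agreement to 1e-4 relative error with an independent quadrature of the
  g-integral form, monotonicity in |t|, and collapse to BF = 1 as the prior
  scale shrinks).
* The exact one-sided binomial test (`binomial_test_one_sided()`) as the
  sign-test companion.

`sequential_bf_stop()` implements Bayes-factor sequential sampling: stop at
the first batch whose BF10 crosses 5 (evidence for H1) or 1/5 (evidence for
H0), otherwise continue to a participant cap.

Two a priori power solvers are provided. `power_t_one_sample()` scans n
under the noncentral-t power function; for d = 0.61, alpha = .05, power =
.90 it returns 25, and for d = 1.47 it returns 6. For the binomial test,
`power_binomial_one_sided()` implements two conventions that genuinely
disagree:

* `method = "exact"` (default): per n, the critical k is the smallest with
  $P(X \ge k \mid p_0) \le \alpha$ and power is evaluated at $p_0 + g$; the
  exact power is sawtoothed in n and the first crossing is returned. For
  g = 0.13 this gives **n = 128**.
* `method = "normal"`: the z approximation with the binomial dispersion
  evaluated at the alternative proportion,
  $n = \lceil ((z_{1-\alpha} + z_{\beta})\sqrt{p_1(1-p_1)}/g)^2 \rceil$,
  the convention used by common power software when the effect is entered as
  g. For g = 0.13 this gives **n = 119**.

Published sample-size statements for this design are typically derived from
the second convention, so reproducing them requires `method = "normal"`;
planning a new study is better served by the exact solver. The discrepancy
is documented rather than hidden precisely because the two numbers differ by
nine participants.

`pearson_r()` and `bonferroni()` round out the layer (correlation of
calibration scores with effect sizes; family-wise correction across
sensitivity rows at $\alpha/m$).

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which the pipeline's guarantees are demonstrated.

What it emulates:

* **Sampling**: nominal 30 Hz with ±20% multiplicative uniform jitter on
  inter-sample intervals (WebGazer-like); the paired lab block samples at a
  regular 250 Hz — a desk-scale stand-in for a laboratory tracker's 1000 Hz
  that preserves proportion estimates, which depend on sample counts only
  through Monte-Carlo resolution.
* **Bias**: per-trial offset = participant-level + trial-level Gaussian
  components. Horizontal defaults (SD 120 and 90 px) give a mean absolute
  per-trial offset of ~120 px, the magnitude webcam studies report for their
  midline corrections. Vertical bias is small (SD 25/20 px) in the two-AOI
  paradigms — where only x is corrected, large vertical bias would push
  off-AOI rates far beyond the 7–15% such studies report — and webcam-scale
  (SD 135/100 px, mean |dy| ≈ 134 px) in the four-AOI paradigm where y is
  corrected. The lab block uses SD 2 px.
* **Noise**: isotropic Gaussian, SD 40 px online / 5 px lab. Per-sample
  webcam noise magnitude is not directly reported in the literature; this
  default was chosen once so that, together with the 5% uniform off-AOI
  rate below, stimulus-phase off-AOI fractions land in the reported 7–15%
  band. It was not revisited afterwards.
* **Glitches**: with probability `off_aoi_rate` (5% online, 1% lab) a sample
  is replaced by a uniform screen position regardless of the looking
  process, and a configurable fraction carries the live-feed flag.
* **Looking processes**: cascade — the probability of looking at the
  eventually chosen AOI rises linearly from 0.5, starting `ramp_ms`
  (default 1000 ms) before the response, to `p_final` (default 0.62) *at*
  the response; novelty — test-phase samples hit the novel AOI with
  probability `p_novel` (default 0.57); visual world — uniform over the four
  AOIs until target-word onset (5000 ms into the display: 1000 ms preview
  plus 4000 ms of carrier sentence), then a linear ramp over 200 ms to
  `p_target` (defaults 0.52 online, 0.71 lab), which then holds. The 200-ms
  ramp completes exactly when the default analysis window opens, so the
  window average equals `p_target`; in the cascade, by contrast, the ramp
  attains `p_final` only at the response moment, so the 100-ms window
  average sits ~0.006 below `p_final` under the defaults — visible in
  recovery checks as a small, explained deficit within Monte-Carlo bands.
* Cascade response times are log-normal (median 3 s, sdlog 0.45), keeping
  essentially all trials inside the [0.5 s, 30 s] filter.

What it does **not** emulate, hence what passing tests do and do not show:
real webcam error is neither Gaussian nor isotropic, drifts *within* trials,
and correlates with head pose, lighting, and face geometry; calibration-phase
behavior is idealized (simulated online calibration scores are ~90%, far
above the ~41% real webcam studies report); there are no blinks, saccade
dynamics, or smooth pursuit — samples are i.i.d. around process targets.
Recovery of injected parameters therefore demonstrates that the *pipeline*
is unbiased and correctly assembled, not that webcam data meet the model.
Gaze is emitted for fixation and stimulus phases only; blank-screen gaps
carry no analyzable gaze and would only distort off-AOI accounting.

Reproducibility: all randomness flows through the single integer seed in
`sim_config()`; identical configurations produce bit-identical datasets, and
`run_pipeline()` output files are byte-identical across repeated runs.

## Numerical and validation choices

* Quadrature for the Bayes factor uses `stats::integrate` over the
  (half-)infinite domain at 1e-8 relative tolerance; the noncentral-t
  density it integrates is itself accurate to ~1e-8, and agreement with an
  independently parameterized fixed-grid quadrature is asserted at 1e-4.
* The d-bound inversion brackets the noncentrality root in
  $t \pm 10\sqrt{n}$ and solves to 1e-9.
* Degenerate inputs error early and explicitly (zero-variance samples,
  mismatched pairs, empty bias tables) except where a missing value is the
  documented contract: a trial with no usable fixation samples yields a
  missing bias estimate and a flagged trial, not a crash; a window with no
  in-AOI samples yields a missing trial result.
* Validation problem sizes were fixed once as the package's demonstration
  conditions: null calibration and parameter recovery run at 200 simulated
  participants per paradigm (18/10/12 trials), where 3 SEM of the grand mean
  is well under a percentage point for the high-rate paradigms; the type-I
  experiment runs 2000 full pipeline replicates at 10 participants × 5
  trials with a 1.2-s median response time, which keeps the whole experiment
  tractable while the rejection rate's Monte-Carlo band (±1.5 points at 3
  SE) is tight enough to detect meaningful miscalibration.

## Known limitations

* The exclusion cascade assumes the documented column schema; converters
  from tracker-specific formats (WebGazer JSON, EyeLink EDF exports) are
  user-side.
* No fixation/saccade event detection: analyses operate on raw estimated
  gaze points, as AOI-proportion designs do; the package is not suited to
  fixation-duration or saccade-trajectory questions.
* The uniform-glitch component slightly attenuates injected preferences
  (glitch samples occasionally land inside AOIs at chance rates); at the
  default 5% rate the attenuation is a fraction of a percentage point and is
  absorbed by the recovery tolerances, but analyses of much noisier streams
  should expect proportion estimates to shrink toward chance.
* One-sided confidence bounds for d use the noncentral-t inversion
  exclusively. Published webcam studies print d intervals whose provenance
  can differ; agreement should be checked before comparing bounds across
  reports.
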