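---
title: "Methods: phasic arousal and decision bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasic arousal and decision bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arousalbias)
```

`arousalbias` analyzes how trial-to-trial fluctuations of phasic arousal,
indexed by the task-evoked pupil response (TPR), relate to perceptual
decision bias. This vignette is the package's own account of the methods:
the models, their assumptions, the tunable parameters, the synthetic-data
generator the tests run on, and the numerical choices made where a design
was genuinely open.

## Task structure assumed throughout

The pipeline is built around a slow event-related yes/no detection task:
trials are organized in blocks of 40 with a signal present on exactly half
of the trials per block; each trial has a 2 s pre-decision baseline, a
decision interval terminated by the button press (deadline 3.5 s;
non-responses are flagged and excluded from behavioral analyses), and an
inter-trial interval drawn uniformly from 4–12 s. These values are the
defaults of `ground_truth()` and can all be overridden.

## Pupil preprocessing

`preprocess_pupil()` applies four steps in a fixed order:

1. **Blink interpolation** (`interpolate_blinks()`): linear interpolation
   across each blink, extended 150 ms before and after (margin
   configurable). Overlapping windows are merged; windows clipped by a
   trace edge are filled flat. Blink/saccade *detection* is an input
   (event lists accompany the trace), not something the package does.
2. **Band-pass filtering** (`bandpass_filter()`): third-order Butterworth,
   passband 0.01–6 Hz. We apply it forward–backward (zero phase) so that
   no lag is introduced into TPR timing; whether the original procedure
   was zero-phase is not documented, so a `zero_phase` flag exposes the
   causal single-pass alternative. Traces shorter than about three time
   constants of the high-pass edge (~48 s at 0.01 Hz) are rejected, since
   the filter transient would dominate.
3. **Artifact-response removal** (`remove_artifact_responses()`): the pupil
   responds to blinks and saccades themselves; these stereotyped responses
   are estimated by finite-impulse-response deconvolution over a 6 s
   post-event window (all event types jointly, least squares, sparse
   design) and regressed out. Event types with fewer than 5 events are
   skipped with a warning. The 6 s window covers the duration of a pupil
   response; event onsets are taken at artifact offset.
4. **Percent-signal conversion** (`to_percent_signal()`): per block,
   `100·(x − mean)/mean`. Because the band-passed trace is already near
   zero-mean, the divisor is the per-block mean of the interpolated,
   *pre-filtering* trace, recorded in step 1. The output has exactly zero
   mean per block.

## TPR quantification and binning

`compute_tpr()` defines, per trial, the baseline as the mean percent
modulation in the 0.5 s before the cue, and the raw amplitude as the mean
in the window −1 s to +1.5 s around the button press minus that baseline.
Slow peripheral (and, for fMRI, hemodynamic) low-pass filtering makes
longer trials produce larger responses without larger neural input, so
amplitudes are residualized on reaction time (`residualize()`, OLS with the
mean added back so binned metrics stay on the original scale); the
`rt_residualization` toggle of the pipeline reproduces the control variant
without this step. `bin_trials()` supports the lowest-40% / middle-20% /
highest-40% scheme (a trade-off between per-bin trial counts and TPR
disparity of the extreme bins) and equally populated quantile bins (4 or
5); ties are broken by the stable order of the trial index, so binning is
deterministic.

## Pupil GLM

`fit_pupil_glm()` estimates the relative contribution of three putative
neural input components to the measured pupil response. Epochs from 1 s
before to 5 s after cue are baseline-corrected (0.5 s pre-cue mean — the
same window as the TPR baseline; the two are assumed identical) and
concatenated. The design has, per trial: a transient at cue; a transient
0.24 s **before** the button press (the documented latency between phasic
brainstem activity and the overt response in primates; configurable); and
a sustained boxcar from cue to choice whose height is divided by the
number of samples in the interval, so that every pre-convolution regressor
sums to 1 per trial and transient and sustained beta weights are
comparable. Each regressor is convolved with the canonical pupil impulse
response

$$h(t) = (t/t_{max})^{w}\, e^{-w\,(t/t_{max}-1)},$$

normalized to peak 1 at `t_max`. The shape parameters are not estimated;
defaults `w = 10.1`, `t_max = 0.93` s are the canonical literature values
and are exposed in the interface. Betas are ordinary least squares;
per-bin fits (`bin_labels`) quantify how the sustained input grows with
arousal.

## Signal-detection analyses

`sdt_metrics()` computes `d' = z(H) − z(F)` and criterion
`c = −(z(H)+z(F))/2` (negative = liberal). Rates of exactly 0 or 1 are
corrected by the log-linear rule (0.5 added to the counts of the affected
signal or noise pair, 1 to its denominator); applying the correction only
at the edges keeps interior rates exactly at their empirical values. A
flag switches to the always-on log-linear variant or to no correction.

`balanced_fraction_yes()` removes stimulus composition as a confound of
the yes-rate: the minimum count over bin × stimulus cells is sampled
without replacement from every cell, the per-bin fraction of yes computed,
and the procedure repeated (default 1000 times, seeded) and averaged.
`nonpreferred_fraction()` defines the preferred option from all trials
irrespective of bin, with a documented tie-break toward 'yes' at exactly
50/50, and `abs_criterion()` gives |c| per bin — the bias measures of
choice when bias signs vary across subjects.

`sequential_poly_regression()` tests whether a metric depends on TPR not
at all (order 0), monotonically (1), or non-monotonically (2): orthogonal
polynomial bases of the bin-level predictor (bin-mean TPR by default, bin
index optionally) are compared by nested-model F-tests on the stacked
group data with subject intercepts. The selected order is the highest
order whose step is significant; the quadratic step is evaluated even when
the linear one is not, because a purely non-monotonic (inverted-U)
dependence has no linear component. Per-subject linear/quadratic
coefficients are returned for group-level testing.

`sliding_window_criterion()` traces the timing of the pupil–criterion
link: a 250 ms window stepped in 25 ms increments (aligned to the button
press), baseline-corrected windowed pupil value per trial, five quantile
bins, criterion per bin, and the Pearson correlation between bin-mean
pupil and criterion per window position.

`paired_permutation_test()` implements the group statistic used
throughout: sign-flips of paired differences, p = fraction of permutations
at least as extreme as the observed mean difference; two-sided by default
(the verbal description of such tests is often one-sided-ambiguous — we
compare |mean|), with exact enumeration available for small n.

## Drift-diffusion modeling

The stimulus-coded DDM is the package's core inferential model:
`dy = (v·s + dc)dt + c·dW` from `y(0) = z·a` on `[0, a]`, response time =
first-passage time + `t0`, per-trial drift `N(v·s + dc, sv)`. Fitting to
RT distributions of *yes* and *no* choices (rather than correct/error) is
what makes the bias parameters (`z`, `dc`) identifiable. The noise scale
`c` is fixed at 1: only ratios to `c` are identifiable.

* **Simulator** (`simulate_ddm()`): Euler–Maruyama with a Brownian-bridge
  boundary-crossing correction — after every step the probability that the
  connecting bridge crossed a boundary within the step is evaluated — which
  removes the `O(√dt)` late-detection bias of naive discrete crossing
  checks. Non-absorbed trials (deadline `t_max`) are flagged.
* **Likelihood** (`ddm_fpt_density()`): the exact series expansion of the
  two-boundary first-passage density, with the small-time and large-time
  forms chosen per evaluation by the standard truncation-error bound
  (absolute tolerance 1e-8 in the fitting path). Drift variability is
  integrated by 20-node Gauss–Hermite quadrature (nodes computed
  in-package by the Golub–Welsch eigendecomposition). Densities are
  floored at 1e-12 inside fits so single outlying trials cannot produce
  infinite deviance.
* **Fitting** (`fit_ddm()`): per-subject maximum likelihood over full RT
  likelihoods, multi-start (default 5 starts: one heuristic, the rest
  jittered) BFGS on transformed parameters (`log a`, `logit z`, `log t0`,
  `log sv`). Each parameter is free per condition, shared, or fixed; the
  default frees `a, t0, v, z, dc` per TPR bin and shares `sv`, mirroring
  the condition design used for arousal analyses. Model comparison uses
  AIC/BIC; a reduced model with `dc` fixed across bins is fittable the
  same way. We deliberately use per-subject ML rather than hierarchical
  Bayesian estimation: hierarchy is motivated by small per-subject trial
  counts, which synthetic data can avoid, and the likelihood machinery is
  fully in-package. No lapse mixture is included by default.
* **Bias dissociation** (`match_bias()`, `mode_shift_diagnostic()`): two
  parameterizations matched on overall P(yes) — one via `z`, one via
  `dc` — are compared through the modes of their analytic RT densities. A
  starting-point bias shifts the modes substantially; a drift-criterion
  bias barely moves them. This is the model-based fingerprint separating
  the two accounts of bias.
* **Trial-level regression DDM** (`fit_regression_ddm()`): the drift of
  each trial is `β0 + β1·S + β2·M + β3·C` with `M`, `C` z-scored trial-wise
  neural covariates (combined neuromodulatory and colliculi responses);
  `a`, `z`, `t0` are fitted but not covariate-dependent.

## fMRI response quantification and pattern statistics

Scalar responses (`trial_scalar_response()`) are the mean over 2–12 s from
cue minus the mean over −2 s up to (not including) 2 s; the half-open
baseline keeps the windows disjoint. RT effects are removed with the same
`residualize()` used for TPR.

Orientation-specific cortical responses use voxel selection by a per-voxel
t contrast (`voxel_tstat()`; the printed form of this statistic in the
methods literature is typographically ambiguous — we implement the Welch
form `(x̄₁−x̄₂)/√(sem₁²+sem₂²)`, with a flag for the literal normalized-mean
difference), the 50-most-positive + 50-most-negative rule with ties broken
by voxel index (`select_voxels()`), and leave-one-out template correlation
(`template_response()`): the held-out trial's pattern is correlated with
the difference of condition-mean patterns built from all other trials.
Pearson correlation is used (the correlation type is not documented; a
rank correlation would be the natural alternative). The template is signed
so that a genuine stimulus response scores positive on both clockwise and
counter-clockwise blocks. Choice-specific variants use the yes-minus-no
template, per-voxel logistic regression (`choice_logistic()`, Eq.
`P(yes) = plogis(β0 + β1 A)`, fitted separately per stimulus condition and
averaged so stimulus effects drop out, with perfect separation flagged),
hemispheric lateralization (`lateralize()`; voxel minus homotopic partner,
with a subject-level flip expressing lateralization with respect to the
hand used for 'yes'; the flip is an involution), and searchlight decoding
(`searchlight_choice()`: linear SVM, cost 1, sphere of voxels strictly
within 10 mm, explicit leave-one-trial-out so the map is exactly
reproducible; "score" is mean cross-validated classification accuracy,
which is what a 0.5 chance level refers to). Spheres with fewer than 3
voxels are masked.

`roc_predictive_index()` converts single-trial scores into the probability
of predicting stimulus or choice (area under the ROC, computed via the
rank statistic, which is identical to the criterion-sweep construction):
the stimulus-predictive index is averaged over choice conditions and the
choice-predictive index over stimulus conditions, removing the respective
confound.

Brainstem analyses operate on trial-by-ROI scalars: probability-ranked ROI
masks retain exactly the 12 voxels with the highest probability of
containing each small nucleus, and ROI series are probability-weighted
averages (`brainstem_roi_mask()`, `roi_weighted_mean()`).
`tpr_brainstem_correlation()` removes fourth-ventricle fluctuations from
ROI responses and signal presence from both sides before correlating, and
computes partial correlations by additionally residualizing each ROI and
the TPR on all other ROIs. `combine_signals()` builds the combined
neuromodulatory (or colliculi) signal as the TPR-regression-weighted sum
of ROI responses, z-scored for use as a DDM covariate. `bin_linear_fit()`
fits the stimulus-independent arousal modulation of residual
choice-specific responses across five TPR bins.

A caveat worth knowing: when one ROI genuinely carries the pupil-linked
component and all ROIs share a latent factor, conditioning on the coupled
ROI induces a *small negative* partial correlation in the uncoupled ROIs
(collider conditioning). The package's tests assert the correct property —
the coupled ROI's partial dominates and uncoupled ROIs show no positive
partial — rather than exact zeros.

## The synthetic-data generator

`ground_truth()` + the `generate_*()` functions produce every input from
known parameters, with full determinism under a fixed seed. A latent
per-trial arousal state ("low"/"high") drives *both* the sustained pupil
input (betas 1.5 vs 4.5 % modulation) and the drift criterion (−0.3 vs
−0.05, with `a = 1.4`, `v = 0.9`, `t0 = 0.3` s, `sv = 0.3`), creating the
pupil–bias coupling the pipeline must detect, on top of the task structure
described above. Pupil noise is white plus an AR(1) drift (ρ = 0.99),
scaled to 1% modulation total — enough low-frequency power to exercise the
band-pass — and blinks are injected as 100–300 ms dropouts (6/min) to
exercise the 150 ms interpolation margins; optional stereotyped post-event
responses exercise the deconvolution step. Voxel patterns are a common
task response plus orientation- and choice-specific random patterns
(amplitudes 0.08 against unit noise, chosen so that the stimulus- and
choice-predictive indices on a 400-trial session land in the realistic
0.6–0.85 range rather than at ceiling) plus i.i.d. noise; ROI responses
are a shared latent factor plus ROI-specific TPR-coupled components plus a
TPR-unrelated fourth-ventricle series. The default pupil sample rate is
50 Hz to keep simulation light; 1000 Hz (as acquired by research eye
trackers) is supported.

What the generator does **not** emulate: raw gaze/eye-position dynamics,
pupil foreshortening artifacts, non-linear blink recovery shapes, fMRI
volume acquisition and physiological noise, spatial autocorrelation of
voxel noise, or non-stationarities (fatigue, learning). Passing tests on
synthetic data therefore demonstrates correctness of the *procedures* and
recoverability of parameters under the stated statistical structure — not
robustness to every artifact of real recordings.

The adaptive staircase (`simulate_staircase()`) is a Bayesian threshold
estimator for the two-interval forced-choice titration used to set
stimulus contrast before the main task: a posterior over log10 threshold
of an assumed Weibull psychometric (slope 3.5, guess rate 0.5, lapse 0.01;
prior sd 0.5 log-units) is updated per trial, each trial is placed at the
current 75%-correct point, and the returned contrast is the 75% point of
the posterior-mean threshold. The original procedure's prior and shape
settings are not documented, so the package treats titration as a
convergence property (observer accuracy at the returned contrast ≈ the
target) rather than an exact replication.

## Numerical choices and problem sizes

Tolerances and scales used by the test suite, stated here as the package's
own choices: simulator/density agreement is checked as a joint
(sub-distribution) Kolmogorov–Smirnov distance < 0.01 at n = 10⁵ trials and
dt = 10⁻⁴ s over a 12-point parameter grid spanning unbiased and biased
regimes; drift-criterion recovery uses 100 replicates of 2 × 1500 trials
(generating Δdc = 0.25) and requires the mean recovered Δdc within ±0.1
with the correct sign in ≥95 replicates; regression-DDM recovery uses 100
replicates of 1500 trials (β2 = 0.2 recovered within ±0.08, β3 = 0 covered
by its confidence band); pupil-GLM recovery is exact (≤1e-6) without noise
and correlates > 0.9 with generating betas across 100 noisy blocks;
cross-validated pattern analyses are verified to sit at chance under label
permutation (leakage control). Generator simulations use an Euler step of
10⁻³ s where only choices/RT summaries matter and 10⁻⁴ s where
distributional agreement is asserted.

## Known limitations

* Per-subject ML fitting needs adequate trial counts (hundreds per
  condition); it does not pool strength across subjects as a hierarchical
  model would.
* The DDM omits across-trial variability of starting point and
  non-decision time, collapsing bounds, and (by default) lapses.
* The sliding-window criterion correlation computes correlations over as
  few as five bin means; it is a timing descriptor, not an inferential
  statistic on its own.
* The staircase targets a single accuracy level and assumes the observer's
  psychometric slope; a badly mis-assumed slope biases the titrated
  accuracy.
* Partial-correlation "isolation" of a coupled ROI is subject to the
  collider effect described above.
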