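---
title: "Validating an overall movement health score against kinematic metrics and functional tests"
author: "movemetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an overall movement health score against kinematic metrics and functional tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(movemetrics)
```

## The problem

Movement health — the body's readiness to execute everyday motions such as
bending, reaching and lifting — is commonly decomposed into mobility (joint
range of motion), stability (control of movement under load) and posture
(joint alignment). Consumer assessments condense a short exercise protocol
into a single 0–100 score. Establishing *concurrent validity* for such a
score means showing that it moves in the expected direction, with
statistically significant strength, against (a) objective kinematic
performance metrics captured by full-body motion capture during the same
protocol, and (b) a battery of clinician-administered functional movement
tests, and that the score is repeatable across back-to-back trials.

`movemetrics` implements that validation pipeline end to end:

1. **Kinematic primitives** (`ellipse_area_95()`, `count_toe_taps()`,
   `robust_extremum()`, `angle_variance()`, `max_trunk_deviation()`);
2. **Activity metric extraction** for the five protocol activities
   (`extract_all()` and the per-activity extractors);
3. **Functional-test scoring** for the thirteen reference tests
   (`assemble_test_scores()` and the per-test rules);
4. **Validation statistics** (`gated_correlation()`, `group_ttests()`,
   `intrasubject_cv()`, `build_report()`);
5. A **synthetic cohort generator** (`simulate_cohort()`) that replaces
   human-subject data with a seeded statistical stand-in.

## Kinematic primitives

**Postural sway.** Sway is the area of the 95% prediction ellipse of
transverse-plane centre-of-mass acceleration. For samples with 2×2
covariance $C$ the package uses the chi-square prediction ellipse

$$A = \pi \, \chi^2_{2}(0.95) \, \sqrt{\det C} \approx 18.82 \sqrt{\det C},$$

which under a bivariate normal model contains 95% of the samples. An
F-based small-sample correction would inflate the area by roughly
$((n-1)\cdot 2 /(n-2)) F_{2,n-2}(0.95)/\chi^2_2(0.95)$; at the thousands of
samples per balance phase typical of 60 Hz recordings the two differ by
well under 1%, so the simpler chi-square form — standard in stabilometry —
is used and tested against a Monte-Carlo containment oracle. A singular
covariance (constant or collinear samples) yields area 0; fewer than three
samples is an error.

**Toe taps.** A tap is one *downward* crossing of the raised-foot toe
height below the plant-foot toe height. The difference signal must travel
from above $+h$ to below $-h$ with hysteresis $h$ = 5 mm (default) before a
tap counts, suppressing sensor jitter; the return upward is not counted,
so one physical ground contact scores one tap. The count is invariant to
a common vertical shift of both traces.

**Outlier-damped extrema.** Joint-angle maxima and minima are taken as the
median of the samples at or beyond the 90th (respectively 10th) empirical
percentile, rather than the raw extremum, to damp isolated spikes. The
percentile boundary uses R's default linear-interpolation definition
(type 7) and even-cardinality medians are averaged; both choices are fixed
for reproducibility. The same decile-median rule is applied uniformly to
every extremum the extractors report — including trunk deviation and
shoulder range of motion — a deliberate interpretation where a narrower
reading (hip/knee/elbow angles only) would also have been possible.

**Variances** are sample variances (denominator $n-1$) everywhere an angle
variance or the plumb-line landmark variance is computed. One consistent
convention is preferable to mixing estimators, and $n-1$ is the standard
small-sample choice.

## Activity metrics

Eighteen metrics summarise the five activities (see
`activity_metric_names()`). Conventions worth stating:

* **Bilateral aggregation** is the arithmetic mean wherever a metric has a
  left and a right instance (balance phases, knees, hips, elbows,
  shoulders).
* **Squat depth** is `min(knee_z) - min(pelvis_z)` per repetition,
  averaged over repetitions; positive when the pelvis descends below the
  knees. The subtraction order is kept exactly as stated in the protocol.
* **Repetition segmentation** is recovered from the driving vertical
  channel (pelvis height for squats, the lower of the two knee heights for
  lunges): 0.5 s moving-average smoothing, dips below 25% of the smoothed
  peak-to-peak range (measured down from the maximum), minima closer than
  1 s merged, each window at least 0.5 s. A flat channel (range
  < 0.02 m) is an error; a mismatch with the expected count (6 lunges,
  6 overhead squats, 3 feet-together squats) is a warning, not a failure,
  because impaired participants may not complete every repetition.
* **Trunk metrics** for lunges and squats span the whole activity;
  only the elbow variance of the overhead squat is restricted to the
  repetition windows, the one metric for which the protocol states a
  repetition-limited window explicitly.
* Single-leg-balance stance phases are required input annotations
  (`balance_left`, `balance_right`); automatic stance detection is out of
  scope. The toe-tap count is averaged over the two phases, so the
  reported metric can be a half-integer.

## Functional-test scoring

Each of the thirteen reference tests keeps its published units and
aggregation rule: means over trials/limbs for the distance and time tests;
variance of the four landmark distances for the plumb line; reach
composites normalised by limb length (dimensionless, unit-invariant) for
the star excursion and upper-extremity Y balance; capped sums for the
timed balance tests (60 s over two Sharpened Romberg trials, 180 s over
six CTSIB conditions); and mean-over-trials sway-ellipse areas for the two
acceleration scores, which reuse `ellipse_area_95()` and therefore inherit
its calibration. All samples recorded during a prematurely ended balance
trial still enter the acceleration score.

Two rules deserve comment. The **hurdle step** protocol grades three steps
per leg (0–3) and aggregates them "into a single score per leg" without
stating the rule; the package uses the median of the three grades, with
the screening-practice convention that any pain grade (0) forces that
leg's aggregate to 0. Both the aggregate function and the pain rule are
arguments of `score_hurdle_step()`, so a different convention is one call
away. The **CKCUES** test is the single test where non-completion is an
explicit score of 0; every other missing test propagates as a missing
value, never as a zero.

## Validation statistics

Normality of every variable is assessed with the Shapiro-Wilk test.
A correlation cell uses Pearson's product-moment coefficient when the
variables involved are normally distributed and Spearman's rank
coefficient otherwise; "the variables" is read as *both* variables of the
pair (the stricter reading), with `gate = "either"` available. Normality
is evaluated on the pairwise-complete subset of each pair, keeping the
gate and the coefficient on identical data. All tests are two-sided at
$\alpha = 0.05$ per cell with no multiple-testing correction, mirroring
standard practice for validity grids; Benjamini-Hochberg adjustment is
available via `p_adjust = "BH"`. A cell *agrees* with the validity
hypothesis when it is significant and its sign matches the hypothesised
direction.

Group comparisons use Student's two-sided t-test with equal variances
(the unqualified convention), with Welch's test behind
`var_equal = FALSE`. Reliability is the intrasubject coefficient of
variation — sample SD over mean of the three assessment trials, in
percent — for subjects with exactly three trials, summarised as mean ± SD
across subjects.

**Null calibration.** `null_calibration()` checks the type-I error of the
gated correlation machinery by correlating features against permuted
scores. Because the features of one cohort are mutually correlated
(they share the latent impairment), permuting the score *once* per
replicate and testing all 33 features would produce clustered significance
events whose pooled rate fluctuates several times more than a binomial
proportion; a tolerance stated in binomial standard errors would then be
meaningless. The package therefore draws an **independent permutation per
(replicate, feature) cell**, making the pooled rate a genuine binomial
proportion with `n_perm × n_features` trials. With 200 replicates × 33
features the observed rate sits at 5.0% with the predicted binomial SD of
about 0.27 percentage points.

## The synthetic cohort

No public dataset accompanies this methodology, so the package ships a
seeded generator whose defaults *are* the study conditions: n = 150
participants split 113 healthy / 17 athlete / 20 movement-impaired, three
assessment trials each, 60 Hz capture. Each participant has a latent
impairment $\theta \in [0,1]$ drawn from a class-conditional Beta
distribution (athlete Beta(2,10), healthy Beta(3,6), impaired Beta(8,4) —
illustrative, configurable) with mobility/stability/posture subcomponents
$m, s, p$ scattered around $\theta$ (zero-sum perturbation, SD 0.07) under
the constraint $\theta = \mathrm{mean}(m,s,p)$.

Impairment enters the kinematics monotonically:

| mechanism | scaling | affected outputs |
|---|---|---|
| squat/lunge depth, joint-angle amplitudes | $\times (1 - 0.6\,m)$ | pelvis depths, hip/knee/shoulder maxima, knee-ground distance |
| trunk deviation amplitude | $\times (1 + 4\,p)$ | trunk maxima and variances |
| COM acceleration SD (mean-reverting noise) | $\times (1 + 5\,s)$ | postural sway, balance acceleration scores |
| toe-tap Poisson rate per phase | $3\,s$ | toe taps |
| elbow-flexion fault amplitude | $32\,s$ deg | elbow maxima and variances |

Centre-of-mass acceleration is an Ornstein-Uhlenbeck process
(correlation time 0.5 s) rather than white noise, so its covariance — and
hence the sway area — is well defined and robust to the sampling rate.
Repetition dips are half-cosine excursions with a flat hold at the bottom
(participants pause at the deepest position), which also makes the
noiseless templates exactly recoverable: at $\theta = 0$ with noise off,
squat depth equals the template depth and the damped knee-flexion maximum
equals the template amplitude. Measurement noise is Gaussian, 0.3° on
angles and 3 mm on positions — representative of inertial motion-capture
error and comfortably below the 5 mm tap hysteresis.

The overall score stand-in is $\mathrm{clip}(95 - 30\,\theta +
\varepsilon, 0, 100)$ with trial noise $\varepsilon \sim N(0, 1.5)$,
placing the intrasubject CV in the 1–3% band typical of repeated
standardized assessments. Functional-test measurements follow linear
latent means in the relevant subcomponent with the hypothesised sign
(e.g. sit-and-reach decreases in $m$, plumb-line landmark SD increases in
$p$, timed balance decreases in $s$ and saturates at the 30 s trial cap,
reproducing the well-known ceiling of the timed CTSIB). Per-test
missingness approximates the published completion counts and is more
likely at higher impairment. Effect sizes were fixed once so that the
qualitative findings — sign structure, class ordering, moderate-to-strong
correlations — emerge at n = 150; the generator is deliberately **not**
calibrated to reproduce any particular correlation coefficients, group
means or CV values, which are empirical properties of real participants
and a proprietary scorer.

What passing tests on this cohort do and do not show: they verify that the
extraction and statistical machinery recover a *constructed* monotone
structure with the right signs and calibrated error rates. They do not
show that real human kinematics have this structure, nor validate any
actual scoring product; real data bring non-stationary sway,
asymmetries, activity-recognition failures and pose-estimation error that
the generator does not emulate.

## Reproducibility and problem sizes

Every random quantity descends from the single cohort seed through
per-participant, per-activity derived seeds, so generation is independent
of evaluation order and `run_pipeline()` at a fixed seed reproduces every
output file byte for byte (numerics are serialised at full `%.17g`
precision). The test suite exercises the Monte-Carlo ellipse oracle at
$10^5$ samples, the brute-force primitive oracles at 1000 random cases
each, segmentation recovery on 300 traces across impairment levels, the
full default cohort (n = 150) for sign structure and group ordering, and
null calibration at 200 replicates per feature — sizes chosen so the whole
suite completes in about a minute while keeping the binomial/Monte-Carlo
error bars tight. `scripts/acceptance.R` recomputes the same quantities
from scratch at any seed.

## Known limitations

* Trace ingestion consumes joint angles and positions that an upstream
  vendor pipeline has already computed; orientation math from raw
  quaternions, sensor fusion and vendor file parsing (e.g. MVNX) are out
  of scope.
* Stance-phase annotations are required inputs; stance detection is not
  implemented.
* The generator's class-conditional Beta parameters and effect sizes are
  illustrative study conditions, not estimates from any dataset.
* The hurdle-step per-leg aggregation rule is a documented convention, not
  a reconstruction of the original clinicians' rule.
* No attempt is made to model the image-to-score neural network whose
  output the overall score stands in for.
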