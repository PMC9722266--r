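---
title: "Models and methods behind pupiladapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pupiladapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pupiladapt` implements, with a fully synthetic data source, the complete
analysis chain of a pupillometry study of force-field reach adaptation:
trial simulation, pupil/gaze preprocessing, trial-feature extraction,
two-state learning-model inference, frame-wise group statistics, and the
experiment-level analyses (change points, set breaks, recall-based splits).
This vignette explains the models, the parameters that matter, the design
choices that were genuinely open, and what passing the package's tests does
and does not demonstrate about real data.

## The task and the physical model

Participants hold a robotic handle and make straight forward reaches (12 cm
in the abrupt design, 10 cm in the others) while a velocity-dependent curl
field perturbs the hand:

$$\begin{pmatrix} f_x \\ f_y \end{pmatrix} =
  \begin{pmatrix} 0 & B \\ -B & 0 \end{pmatrix}
  \begin{pmatrix} v_x \\ v_y \end{pmatrix},$$

with viscosity $B > 0$ for a clockwise (CW) field. Because the force matrix
is antisymmetric, the field performs no mechanical work; the package's
recorded force channels preserve $f \cdot v = 0$ to machine precision, and a
test asserts it.

The simulator's forward component is a minimal-jerk profile of 600 ms
(configurable through the movement-time model); the lateral component is a
point mass driven by the field, the learner's feedforward compensation
$-\hat{B} v_y$, a lateral PD feedback, and Gaussian execution-force noise,
integrated by RK4 at a 1 ms substep. Two choices here deserve comment:

* **Effective lateral mass: 0.3 kg.** The mass only matters through the
  ratio of inertial to viscous forces. On channel trials the recorded wall
  force differs from the feedforward command by an inertial term
  $\approx m\,|\dot a_y|\,\hat{B}/k$; at 0.3 kg (a light handle) this bias
  is below $7\times10^{-4}$ viscosity units for both channel
  configurations, so the learning-index identity (below) holds at its
  analytic tolerance, and free-reach deviations come out at a realistic
  millimetre scale.
* **No feedback against the channel.** Visuomotor corrections respond to
  *perceived* path error. The channel (a stiff spring–damper along the
  straight path, 7000 N/m / 30 N s/m in the abrupt design, 2500 / 25 in the
  others) clamps deviations to micrometres — far below perceptual
  threshold — so the PD feedback is inactive on channel trials. A position
  servo pressed into the wall would shade the measured compensation by
  $k/(k+K_p)$ and break the identity that full compensation reads out as
  exactly $B$.

The learning index of a channel trial is the lateral force on the channel
at the moment of peak tangential velocity, divided by that peak velocity —
a viscosity. `force_x` records the force the environment applies to the
hand (the robot's command force), which makes the index $+B$ under full CW
compensation; recording the hand-on-wall force instead would flip its sign
and contradict the convention in which learning curves rise toward $+B$.

## Schedules

`make_schedule()` reproduces the six designs trial-for-trial: the abrupt
null–field–null design (five blocks of 59/59/59/44/59 trials, the first and
last two of each block measuring the pupillary light reflex; field on from
the 11th reaching trial of block 2 to the 10th of block 4), the three
switching designs with their printed CW/CCW trial sets, the gradual design
(5% of full strength added every 11 trials from the 16th trial of block 2,
abrupt removal at the 11th trial of block 7), and its variant ending in a
50-trial channel phase. Tests compare the generated perturbation vectors
against the printed trial lists element-for-element.

"Channel trials in 20% of trials" is implemented as **one channel trial per
5-trial cycle**, randomly placed within the cycle from a dedicated seeded
stream with a minimum gap of one trial between channels. This reconciles
the 20% rate with learning indices being measured "once in a cycle", and
makes cycle-level learning curves well defined. The schedule stores the
*environment* viscosity on channel trials (the channel physically replaces
the field for that trial); change points are trials where the environment
viscosity jumps by more than half the design's full strength within a
block, so the 5% increments of the gradual design are not change points and
block-boundary changes are excluded.

## The generative learner and pupil model

Adaptation follows the canonical two-state error-driven learner: fast and
slow states $x_i(n+1) = A_i x_i(n) + B_i e(n)$ with net adaptation
$x = x_f + x_s$ and error $e = f - x$ in field units normalized to 1;
channel trials clamp the error ($e = 0$, retention-only update).
Ground-truth defaults $A = (0.90, 0.995)$, $B = (0.15, 0.02)$ give a
realistic learning curve (asymptote $\approx 0.85$) with a visible
aftereffect; cohorts jitter all participant parameters (±10% relative, on
scales that preserve the ordering constraints $A_s > A_f$, $B_f > B_s$).

The pupil has a tonic and a phasic component, both in percent of the
participant's light-reflex range:

* **Tonic (uncertainty-like).** A latent level relaxes geometrically toward
  a floor (default 40%, decay 0.85/trial), receives a fixed **novelty
  bump** (+10%) on the first trial of each block, and is pushed up by
  **excess surprise** ($2\%$ per unit of $\max(s-1, 0)$). Surprise is the
  observed error magnitude relative to a running expectation updated at
  habituation rate 0.2 — so repeated large errors stop being surprising.
* **Phasic (surprise-like).** Each trial adds $4\% \times \min(s, 6)$ times
  a gamma-family impulse response (shape 10.1, peak 930 ms after movement
  onset — the standard psychophysiological kernel family, with the peak
  late enough that the 300–700 ms dilation-velocity window samples the
  rising phase). AR(1) measurement noise (SD 0.5%, $\phi=0.95$) and
  trial-level tonic jitter (SD 1%) are added, the percent trace maps
  affinely onto millimetres via the participant's calibration range
  (defaults 2–7 mm), and Poisson blinks (0.2/trial) overwrite samples with
  a near-zero artifact as a video eye tracker would.

Channel trials produce neither a learning update nor a surprise sample
(their error is clamped by construction); the latent expectation simply
persists and the tonic level decays.

Reaction time and movement duration are linear in the tonic elevation
(20 ms and 10 ms per 5% excess, plus noise), which is what makes the
set-break contrast (early trials slower *and* more dilated) recoverable.
The post-study questionnaire is simulated as a per-block Bernoulli report
whose probability is logistic in the participant's mean tonic elevation in
that block, giving the recall median split a recoverable ground truth.

Only the final 1.5 s of the pre-cue hold period is recorded. The real task
waits a variable 3–11 s, but no modeled quantity depends on that duration
and the baseline window is the final 1.0 s before the go cue, so trimming
the recording keeps memory flat without changing any downstream number.

## Preprocessing

The conditioning chain follows standard pupillometry practice: 100 ms
before and 150 ms after each blink are discarded and refilled by monotone
piecewise-cubic (PCHIP) interpolation; gaze is smoothed with a 35 ms-FWHM
Gaussian; eye velocity for saccade detection comes from a second-order
Savitzky–Golay filter with a 55 ms frame (11 samples at 200 Hz) followed by
first differencing, on visual-angle coordinates
($\theta = \operatorname{atan}(\text{offset}/\text{eye distance})$); the
saccade criterion is a 30 deg/s threshold on the Euclidean speed of the two
axis velocities, with sub-10 ms gaps merged. The pupil is smoothed with a
235 ms-FWHM Gaussian, normalized to percent of the light-reflex range
(per-block bright troughs and dark peaks averaged across blocks, so 0%
anchors at the constriction trough and 100% at the dilation peak), and
differentiated. All convolutions use reflection padding, which avoids edge
attenuation of the baseline estimate; trials are processed independently
(the robot repositions the hand between trials, so interpolation across
boundaries would be meaningless).

Choices the source methods leave open, exposed as knobs: the baseline
window is the final 1.0 s before the go cue; the saccade-exclusion
"movement period" is [onset, offset] from the analysis-grade 10%-of-peak
segmentation; the 300–700 ms dilation-velocity window is fixed across
designs.

## Statistics

*Frame-wise tests.* Paired t-tests at every frame of the onset-locked
dilation-velocity traces (baseline block vs the first five perturbed
trials), with Holm–Bonferroni (step-down, familywise $\alpha=0.05$) and
Benjamini–Hochberg (step-up, FDR $q=0.05$) masks computed through
`stats::p.adjust` and verified in tests against brute-force evaluation of
the defining inequalities. Holm rejections are provably a subset of BH
rejections at $\alpha = q$; a 10,000-vector property test asserts it.

*Cluster-mass permutation.* Clusters are maximal same-sign runs of frames
with $|t|$ above the two-sided $p=0.01$ t-quantile; the mass is the sum of
t in the run; the null is the maximum absolute mass over sign-flips of the
subject difference traces. For 12 or fewer subjects all $2^n$ flips are
enumerated (no Monte-Carlo error); otherwise 10,000 random flips by default
with the add-one estimator, so p-values are never zero and the test is
valid by construction. The calibration suite uses 500 null datasets of 20
subjects × 100 frames at 2,000 permutations per dataset — enough that
Monte-Carlo error is negligible against the binomial width of the
acceptance band. Frames containing missing subjects are dropped from
cluster formation, not imputed.

*Two-state inference.* Least squares on the channel-trial learning-index
series (normalized by full field strength), optimized by multi-start BFGS
in a transformed space where the ordering constraints hold by construction
(logit-scaled retentions, gap-parameterized rates). Twenty seeded starts
plus a high-precision polish give machine-accurate recovery on noiseless
series; bootstrap refits (resampling participants, refitting the resample
average, simulating forward through washout) warm-start at the point
estimate with one extra random start and a looser tolerance, which changes
band quantiles by far less than their Monte-Carlo width. The washout band
is the 2.5/97.5 percentile band; the headline statistic is the longest run
of consecutive washout trials on which the actual group average falls below
the lower bound. The percent-change transform maps a phase onto 0 (phase
start) to 100 (plateau = mean of the last five pre-change cycles), flipping
washout about its plateau; the latency to $x\%$ change is the trial of the
$n$-th exceedance ($n = 10$ for kinematic error, 3 for the learning index).

*Mixed models* (change-point trends, the error→pupil washout prediction,
block × subgroup comparisons) delegate to `lme4`/`lmerTest` (REML,
Satterthwaite df). Models that come back singular fall back to documented
simpler structures and are flagged. The block × subgroup interaction codes
the subgroup ±½ so that each block's interaction coefficient is directly
the between-group difference in that block; the random-slope contribution
of the change-point count is assessed by a 2-df restricted-likelihood ratio
test against the model without it.

## Problem sizes used by the test and acceptance suites

Cohort-level checks run the abrupt design at its published size (n = 28)
with the generator defaults; statistical calibration suites use 500 null
datasets (cluster type-I), 100 noisy replicates (two-state recovery), 300
bootstrap draws (band coverage; the analysis default remains 1,000), and
1,000 random series (latency oracle). These sizes were chosen so each suite
gives stable verdicts at conventional Monte-Carlo error.

## What the synthetic cohort does and does not show

The generator reproduces, with recoverable ground truth, the structure the
analyses are designed to detect: decaying errors with aftereffects, a
surprise-driven phasic dilation locked to movement onset, tonic bumps at
block starts with accompanying RT/MT slowing, surprise habituation across
repeated change points, and recall reports coupled to tonic uncertainty.
It does **not** emulate: pupil foreshortening with gaze angle, luminance
confounds beyond the light-reflex calibration, fatigue or vigilance drifts,
uncertainty-modulated surprise after set breaks (in the generator early
block trials are *not* extra-surprising, so the early/late dilation-velocity
contrast is null by construction), trial-history effects on feedback
control, or non-Gaussian error distributions. Passing tests therefore
demonstrates that the pipeline recovers what the generative model puts in
at realistic noise levels — not that the pipeline's assumptions hold for
any particular real dataset.

## Numerical notes and degenerate inputs

Deblinking with a fully masked trace is an error; blinks touching the trace
edge extend the nearest surviving value and are flagged. Zero-variance
paired differences report the degenerate-limit p of 0 with a flag;
constant-zero difference traces yield an empty cluster list. Flat learning
series pin both learning rates at their lower bound and are flagged
unidentifiable. Channel trials with peak speed below 1 cm/s yield a missing
learning index. Sub-sample smoothing kernels warn and return the input.
All randomness in the package flows from explicit integer seeds, with
child-stream derivation keeping every seed below $2^{31}$.
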