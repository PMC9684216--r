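---
title: "The vtnet model: interhemispheric competition in bimanual tactile detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vtnet model: interhemispheric competition in bimanual tactile detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`vtnet` simulates tactile detection on the two hands with a firing-rate
network of two symmetrical hemispheres.  Each hemisphere represents one hand
and contains:

* a **tactile map** and a **visual map** (by default 20 x 20 units each, at
  0.5 cm spacing, i.e. a 10 cm x 10 cm patch of hand-centred space).  Every
  unit has a Gaussian receptive field (RF) with unitary peak gain; the RF
  standard deviation is set so the half-maximum RF diameter is 2.25 cm, the
  midpoint of the 2-2.5 cm range typical of hand tactile RFs.  Units of one
  map interact through Mexican-hat lateral synapses (difference of Gaussians
  of RF-centre distance: narrow excitation, broader weaker inhibition), so a
  punctate stimulus ignites a compact activity bump that does not spread.
* a single **multisensory unit** pooling the whole tactile and visual maps
  through spatially uniform feedforward weights (`w_ff_*`), and returning
  spatially uniform, weaker feedback (`w_fb_*`).  Its tactile and visual RFs
  therefore cover the entire hand.
* an **inhibitory interneuron** driven by the *opposite* hemisphere's
  multisensory unit through a callosal projection (`w_inter`) with a 10 ms
  transmission delay, and inhibiting the unisensory maps of its own
  hemisphere (`w_inh_*`).  This closed loop implements the competition
  between the two hand representations.

Every unit follows leaky first-order rate dynamics with a logistic
activation,

$$\tau \,\dot u = -u + \mathrm{net}(y), \qquad
  y = \frac{1}{1 + e^{-a (u - \theta)}},$$

integrated with explicit Euler steps.  The network's governing equations in
the predecessor-model family are published only in a supplement that is not
available, so this standard leaky-sigmoid form was adopted deliberately; it
reproduces every qualitative property the architecture is described to have.
Two consequences of this choice are documented here:

* **The silent state is approximate.**  A pure logistic has
  $y(0) = 1/(1+e^{a\theta}) > 0$, so the resting network sits at a tiny basal
  activity (about $10^{-4}$ in the unisensory maps, $10^{-2}$ in the
  multisensory unit) rather than exactly zero.  The resting state is
  *perceptually* silent: all activities are far below the detection
  threshold.  No rectification is applied, matching the closed-form sigmoid
  values used in the unit tests.
* Unisensory and multisensory units use a smooth slope (graded responses);
  the interneuron's slope is four times the unisensory slope, giving it the
  rapid resting-to-saturation transition that enforces a decisive
  competition.

## Perceptual readout

A trial is integrated to steady state (maximum per-step activity change
below `steady_tol`); activity is only then interpreted.  Each hand's
**Tactile Awareness Degree (TAD)** is positive only when the tactile map's
peak activity *and* the multisensory unit's activity concurrently exceed the
detection threshold (a single threshold, 0.5, shared by both criteria and by
both hands); when positive, the TAD equals the multisensory activity.  The
4AFC report is the sign pattern of the two TADs: bright-hand only, dim-hand
only, both, or none.

## Stimuli and noise

The 4AFC task crosses four tactile conditions (touch on the bright-associated
hand `B`, the dim-associated hand `D`, both `BD`, none `N`) with four visual
conditions (`none`, `both`, `brightLED`, `dimLED`).  The baseline block uses
only the four tactile conditions; the visuo-tactile (VT) block uses all 16.
All stimuli are punctate and delivered at the grid centre; the brief tactile
taps of the behavioral task are modelled as constant drives held to steady
state, since the readout is steady-state activity.

Each active stimulus is scaled by an independent multiplicative noise factor
$\max(0, 1 + \varepsilon)$, $\varepsilon \sim \mathcal N(0, 0.2)$, drawn
once per stimulus per trial.  The multiplicative reading of the
"variance 0.2" input noise was chosen (over an additive one) because it
leaves no-stimulus trials exactly silent, which is what makes the model's
100% correct rejection of catch trials structural rather than statistical.
A per-time-step noise draw would be ill-defined here because the readout
waits for a steady state.  Visual cues come in two fixed intensities with
the perceived-brightness ratio 2.5:1.

Because the noise multiplier has unbounded-from-below Gaussian support, *no*
finite visual strength is detected on literally 100% of draws: the
multiplier falls below any fixed fraction of nominal with small but nonzero
probability (e.g. below 0.1 on about 2.2% of draws).  The dim visual
strength is therefore placed at ten times the noise-free detection minimum,
on the plateau where visual detection exceeds about 97%, and the bright cue
at 2.5 times that.  This is the closest realizable analogue of the stated
always-detected visual cues.

## Cohorts, jitter, and calibration

A simulated cohort (16 subjects by default, 20 repetitions per condition)
adds two sources of variability:

* **Subject-level synaptic jitter**: every connection $w$ of the model is
  perturbed once per subject by $\mathcal N(0,\ \mathrm{sd} = 0.4\,|w|)$ and
  clipped to preserve its sign.  The stated "variability of 40% of the
  synaptic efficacy" is dimensionally ambiguous between an sd and a
  variance; the sd reading keeps perturbations proportional to efficacy and
  dynamically stable, and is the default (`jitter_as = "variance"` switches
  readings).  "Each connection" is read literally: lateral kernels,
  feedforward, feedback, callosal and inhibitory weights are all jittered.
* **Trial-level stimulus noise** as above.

The free synaptic weights (`w_ff`, `w_fb`, `w_inter`, `w_inh`, lateral
amplitudes, sigmoid shapes) are not published for this model; the shipped
defaults were produced by the package's documented calibration procedure:

1. Hand-tune the weights to satisfy the architecture's qualitative
   constraints: a single unisensory stimulus substantially excites the
   multisensory unit; feedback is too weak to produce phantom percepts in
   the unstimulated modality; bilateral stimulation can activate both
   hemispheres simultaneously even under moderate intensity differences;
   the resting network is perceptually silent.  A deliberate quantitative
   choice within these constraints: the multisensory detection criterion
   binds slightly before the tactile-map criterion (the noise-free stimulus
   threshold through the multisensory branch is a few percent above the
   tactile-map one), so that weakening tactile feedforward weights by 20%
   produces the intended few-point drop in unimanual hit rates rather than
   none at all.
2. **Tactile efficacy** is then the minimal stimulus strength whose cohort
   unimanual hit rate reaches the 80% target (within +/-2 percentage
   points), found by bisection with common random numbers
   (`calibrate_tactile_efficacy()`), mimicking the adaptive per-participant
   thresholding of the behavioral protocol.
3. **Visual efficacy** is set from the noise-free visual detection minimum
   as described above (`calibrate_visual_efficacy()`).

With these defaults the baseline cohort reproduces the intended pattern:
about 80% unimanual hits, exactly 100% correct rejections on catch trials,
and a bimanual split of roughly 60% both / few % none / the rest divided
near-evenly between the two unilateral reports.

## Plasticity presets

Crossmodal-exposure hypotheses are encoded as static weight presets applied
to the basal matrices (`apply_preset()`), not as online Hebbian learning —
matching how the hypotheses were originally tested, by manually setting
parameters.  The Hebbian induction narrative (training thresholds, exposure
dynamics) is therefore out of scope here.

* `H1A_ff_strengthen`: feedforward weights of the bright-hand hemisphere
  x1.8, dim-hand x1.1 (sweepable over +50-80% / +10-30%).  Both modalities
  of a hemisphere are scaled together, reading the strengthened
  "feedforward connectivity" as a whole.
* `H1B_reorganize`: in both hemispheres, visual feedforward x1.2 and
  tactile x0.8, conserving the summed feedforward efficacy exactly (the
  basal tactile and visual weights are equal).
* `H2_interhemispheric`: the directed bright-to-dim competition pathway
  x1.5 and dim-to-bright x1.1.  Each directed pathway's excitatory limb
  (callosal projection) and inhibitory limb (interneuron weights) are
  scaled by the same factor, since a single percentage is attributed to
  the pathway.
* `H3_combined`: H1B followed by H2.

Presets are applied to the basal matrices *before* per-subject jitter; with
a fixed master seed the same subject-level jitter stream is reused across
presets, yielding paired cohorts.

## Bias and fit metrics

For each visual condition $C$ of the VT block, the baseline-corrected
response rate of the bright-associated hand is

$$B^{corr}_C = (B^{1hand}_C + B^{2hand}_C + B^{none}_C)
             - (B^{1hand}_{BL} + B^{2hand}_{BL} + B^{none}_{BL}),$$

the sum of the unimanual hit rate, the bright-only rate on bimanual trials,
and the bright false-alarm rate on no-touch trials, VT block minus baseline
block; $D^{corr}_C$ likewise for the dim hand, and the **lateralization
bias index** is $LBI_C = B^{corr}_C - D^{corr}_C$.  Positive values mean
responses shifted toward the bright-associated hand.

The **MSE** fit statistic is the mean squared difference between two
response tables over every condition x response cell, reported x100 (the
percent-scale convention, chosen so that published MSE magnitudes of a few
percent correspond to proportion-scale tables; `scale` is an argument).
The package ships *no* transcribed human reference table — the published
group matrices are figure-only data — but accepts one as CSV
(`read_reference_table()`) with the documented schema.

## Numerical choices

* Explicit Euler, `dt = 0.5` ms, time constants 20 ms (unisensory,
  multisensory) and 10 ms (interneuron), callosal delay 10 ms (an exact
  multiple of `dt`; the delay line is a step-indexed ring buffer).
* Steady state: maximum per-step activity change below `1e-5`, checked only
  after the delay line has filled; the integration horizon `t_max` is
  600 ms.  The competition loop (two steep interneurons coupled through
  delays) relaxes through a damped oscillation on bimanual trials, and a
  400 ms horizon left a fraction of near-symmetric bimanual trials flagged
  unconverged; 600 ms absorbs them.  Non-convergence at the horizon is
  flagged in the state and propagated into trial records, never silently
  accepted.
* Self-connections in the lateral kernel are kept (the plain DoG value at
  zero distance); their effect is absorbed by the weight calibration.
* Trials are integrated from the resting state (all states at zero).
* Fixed-point correctness is tested against an independent root-finding
  oracle on a miniature 3 x 3 network, at a tightened tolerance
  (`steady_tol = 1e-9`) where the Euler path and the root solve agree to
  `1e-6`.

## Problem sizes used in tests and reproduction

Property and unit tests run on reduced networks (8 x 8 or 3 x 3 grids) and
small cohorts, since the properties they check (symmetry, determinism,
monotonicity, oracle equivalence) do not depend on scale.  The cohort-level
behavioral checks and the reproduction script use the full protocol — 16
subjects x 20 repetitions on the 20 x 20 network — except the directional
bias checks for the H2/H3 presets, which use a reduced paired cohort (8
subjects x 8 repetitions); the bias directions are large relative to
Monte-Carlo error at that size.

## What the generator does and does not emulate

The synthetic cohort emulates inter-subject synaptic variability and
trial-to-trial stimulus variability, under the idealizations listed above:
point stimuli at the hand centre, steady-state readout (no reaction times,
no stimulus-duration effects), no postural or proprioceptive signals, no
carry-over between trials (no adaptation, learning or fatigue within a
block), and hypothesis presets instead of learning dynamics.  Passing tests
therefore show that the *architecture plus calibration* reproduces the
target behavioral pattern, not that real cortical dynamics are captured;
in particular the human data's block-order and learning-trajectory effects
are outside what this simulator can exhibit.

## Known limitations

* The absolute weight values are calibration products, not measurements;
  only their qualitative relations are constrained.
* The model reports only tactile 4AFC responses; visual detections are not
  reported (visual cues are task-irrelevant in the task).
* TAD magnitude beyond its sign is not used in the report, as only the
  binary use is defined by the perception rule.
* With a single multisensory unit per hemisphere, "bump position" plays no
  role: spatial biases within a hand are outside the model's scope.
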