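# vtnet

Firing-rate simulation of **interhemispheric competition in bimanual tactile
detection**, for computational and cognitive neuroscientists studying
visuo-tactile (VT) interactions.

Human observers performing a four-alternative forced-choice (4AFC) task —
"did you feel a tap on the left hand, the right hand, both, or neither?" —
are biased by task-irrelevant visual cues flashed at the hands, and remain
biased toward the hand that was paired with the *brighter* cue even on
later touch-only trials.  `vtnet` implements a neural-network account of
this phenomenon and the machinery to test which synaptic changes can
produce it.

## The model

Two symmetrical hemispheres, each representing one hand, contain:

* tactile and visual **topographic maps** (20 × 20 units, Gaussian
  receptive fields with half-max diameter 2.25 cm, Mexican-hat lateral
  connectivity `L_ex exp(-d²/2σ_ex²) - L_in exp(-d²/2σ_in²)`);
* a single **multisensory unit** *M* pooling both maps through uniform
  feedforward weights *Wm* and returning weaker uniform feedback *W*;
* an **inhibitory interneuron** driven by the *opposite* hemisphere's
  multisensory unit (weight *Wi*, callosal delay 10 ms) and inhibiting its
  own hemisphere's maps (weight *I*) — the competition between the two
  hand representations.

Units follow leaky first-order dynamics with logistic activation,
`τ u̇ = -u + net(y)`, `y = 1/(1+e^{-a(u-θ)})`, integrated by explicit Euler
to steady state.  A touch on one hand is *perceived* when the tactile map
peak **and** the multisensory unit concurrently exceed a detection
threshold; the per-hand Tactile Awareness Degree (TAD) then equals the
multisensory activity, and the sign pattern of the two TADs is the 4AFC
report.

Cohorts of simulated subjects add synaptic jitter (sd = 40% of each
connection's efficacy) and per-stimulus multiplicative noise
(`max(0, 1+ε)`, `ε ~ N(0, 0.2)`).  Crossmodal-exposure hypotheses are
static weight presets: feedforward strengthening (`H1A`), constant-sum
visual/tactile reorganization (`H1B`), asymmetric interhemispheric
strengthening (`H2`), and their combination (`H3`).  Bias is quantified by
the lateralization bias index per visual condition *C*,

```
LBI_C = Bcorr_C - Dcorr_C
Bcorr_C = (B1hand_C + B2hand_C + Bnone_C) - (B1hand_BL + B2hand_BL + Bnone_BL)
```

(hit rate + unilateral-on-bimanual rate + false-alarm rate for the
bright-associated hand, VT block minus baseline block; `Dcorr` likewise for
the dim-associated hand).  Model-versus-behavior fit uses the mean squared
error over all condition × response cells (×100, percent scale).

See the vignette `vignettes/vtnet-model.Rmd` for assumptions, calibration,
and numerical choices.

## Worked example

```r
library(vtnet)

cfg <- vt_default_config()          # calibrated network + stimulus strengths
res <- run_experiment(cfg$params, preset = "baseline", blocks = "baseline",
                      n_subjects = 16, reps = 20, master_seed = 1,
                      tactile_strength = cfg$stimuli$tactile_strength,
                      visual_bright_strength = cfg$stimuli$visual_bright_strength)
tab <- res$tables$baseline
subset(tab, select = c(tactile, visual, p_bright_only, p_dim_only, p_both, p_none))
```

```
  tactile visual p_bright_only p_dim_only  p_both p_none
1       B   none      0.825000   0.000000 0.00000 0.1750
2       D   none      0.000000   0.800000 0.00000 0.2000
3      BD   none      0.178125   0.178125 0.58125 0.0625
4       N   none      0.000000   0.000000 0.00000 1.0000
```

Reading: unimanual taps are detected on ~80-82% of trials (the calibration
target is 80%), catch trials are rejected on 100% of trials (multiplicative
noise leaves zero input silent), and simultaneous bimanual taps are fully
detected on ~58% of trials, with most errors being unilateral percepts —
the competition between hemispheres plus stimulus noise makes one hand's
representation win.  (Proportions vary by ± a few percent with the master
seed; this is the output for `master_seed = 1`.)

Applying a plasticity preset and computing the bias:

```r
h3 <- run_experiment(cfg$params, preset = "H3_combined",
                     blocks = c("baseline", "VT"),
                     n_subjects = 8, reps = 8, master_seed = 2,
                     tactile_strength = cfg$stimuli$tactile_strength,
                     visual_bright_strength = cfg$stimuli$visual_bright_strength)
compute_lbi(h3$tables$VT, h3$tables$baseline)
#>      visual     Bcorr     Dcorr       LBI
#> 1      none -0.062500 -0.031250 -0.031250
#> 2      both -0.015625 -0.015625  0.000000
#> 3 brightLED  0.125000 -0.062500  0.187500
#> 4    dimLED -0.093750  0.109375 -0.203125
```

Positive LBI = responses shifted toward the bright-associated hand; at this
small demonstration cohort (8 subjects × 8 reps) only the strong brightLED
bias resolves clearly above Monte-Carlo noise.

## Command line

A thin CLI over the same functions lives at `inst/cli/vtnet.R`:

```sh
Rscript inst/cli/vtnet.R calibrate --target 0.8 --out cal.yaml
Rscript inst/cli/vtnet.R simulate --config cal.yaml --preset H3_combined --block both --out runs/h3
Rscript inst/cli/vtnet.R report --run runs/h3 [--reference human_table.csv]
```

`simulate` writes `records.csv`, `response_table_<block>.csv` and
`run_meta.json`; `report` writes `bias_summary.csv` and, when a
user-transcribed behavioral reference table is supplied (CSV with columns
`tactile, visual, p_bright_only, p_dim_only, p_both, p_none`; rows summing
to 1), `mse_report.json`.  No human reference table ships with the package.

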