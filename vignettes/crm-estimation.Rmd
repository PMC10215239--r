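---
title: "Estimating compensatory reserve from pulse waveform morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating compensatory reserve from pulse waveform morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmpulse)
```

## The problem

The compensatory reserve measurement (CRM) is a triage index on a 0–1
scale describing how much physiological compensation a patient has left
before hemodynamic decompensation: 1 means a full reserve, 0 means the
threshold of decompensated shock. Because compensatory mechanisms hold
standard vital signs nearly constant during early hemorrhage, CRM must be
inferred from subtler material — the beat-to-beat morphology of the
arterial pulse waveform.

The experimental model behind CRM is lower body negative pressure (LBNP):
a healthy subject's lower body is sealed in a vacuum chamber and exposed
to a staircase of increasingly negative pressures, which redistributes
blood volume away from the torso and safely simulates progressive
hemorrhage. The subject's decompensation pressure defines their personal
endpoint, and the ground-truth label at any chamber pressure is

$$\mathrm{CRM} = 1 - \frac{\mathrm{LBNP}}{\mathrm{LBNP_{HDD}}},$$

where $\mathrm{LBNP_{HDD}}$ is the pressure at which that subject
decompensates. CRM is 1 at baseline, 0 at the decompensation step, and
stepwise non-increasing through a session.

`crmpulse` implements an *explainable* estimation pipeline: named
morphological features, a transparent information-theoretic feature
ranking, and classical regression models whose inputs can be inspected —
in deliberate contrast to convolutional black-box approaches to the same
problem.

## Pipeline overview

1. **Simulate** an LBNP cohort with per-beat ground-truth labels
   (`sample_cohort()`, `simulate_session()`).
2. **Preprocess**: zero-phase FIR lowpass (`lowpass_fir()`), foot-to-foot
   beat segmentation (`detect_beats()`), landmark location
   (`locate_landmarks()`).
3. **Extract** the 54-feature catalogue per beat (`extract_features()`,
   `build_table()`).
4. **Rank** features by minimal-redundancy maximal-relevance
   (`rank_mrmr()`).
5. **Train** one of six regression families on the top-k features
   (`fit_crm_model()`, `train_matrix()`).
6. **Evaluate** with identity-line and conventional regression metrics
   (`perfect_metrics()`, `linear_metrics()`, `evaluate_matrix()`), or run
   everything at once (`run_experiment()`).

## The synthetic cohort generator

Real LBNP datasets with decompensation endpoints are collected under
restricted-access human-subject protocols, so the package ships a
generator that emulates the statistical structure such studies describe,
with known ground truth.

**Protocol.** Nine steps from 0 to −100 mmHg, 5 minutes per step
(`make_protocol()`). The intermediate pressures
`r paste(lbnp_default_ladder, collapse = ", ")` mmHg follow the common
staircase convention of 15 mmHg decrements that coarsen to 10 mmHg below
−60; the ladder is fully configurable. Sessions truncate at the subject's
decompensation step, drawn from groups 4–8 (the distribution extremes are
too sparse in practice to model).

**Beat model.** One cardiac cycle is a diastolic baseline plus two
positive log-concave (Gaussian) components: the systolic ejection wave
and a delayed reflected wave, on a slowly decaying diastolic run-off.
This shape guarantees, in the noise-free limit, a systolic peak followed
by at least one curvature reversal — precisely the structure the landmark
detector must find — and its landmarks have closed-form positions that
the test suite recovers independently by root-finding the analytic second
derivative.

**Effect sizes.** Three monotone links tie morphology to the label; all
are configurable, with defaults chosen to be strong enough that a
ten-feature model can recover CRM on held-out subjects yet leave realistic
overlap between adjacent steps:

* pulse pressure shrinks linearly to 50% of baseline at CRM = 0
  (progressive central hypovolemia reduces stroke volume);
* heart rate rises linearly by 40% at CRM = 0 (baroreflex tachycardia);
* the half-rise→inflection delay (HRIP) contracts to 55% of baseline at
  CRM = 0, implemented by narrowing the systolic component (faster
  ejection under sympathetic drive), with the reflected wave arriving
  correspondingly earlier.

**Subject variability.** Baseline systolic pressure ~ N(125, 10) mmHg,
pulse pressure ~ N(45, 6) mmHg, heart rate ~ N(65, 8) beats/min, baseline
HRIP ~ N(0.25, 0.025) s, all truncated to physiologic ranges. Measurement
noise is additive Gaussian (default sd 1 mmHg) and baseline wander a
0.2 Hz sinusoid of 2 mmHg amplitude — enough to make the lowpass stage
earn its keep. All randomness flows from one cohort seed; per-subject
seeds are derived deterministically.

**What the generator does not emulate:** respiration coupling,
arrhythmias and ectopic beats, motion artifacts, baroreflex dynamics
(within-step adaptation), device-specific transfer functions, or any
closed-loop physiology. Within-step labels are constant (the staircase
"theoretical CRM"); no interpolation across transitions. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the
structure this generator encodes — not clinical performance on human
data.

## Preprocessing choices

* **Filter**: Hamming windowed-sinc FIR, 101 taps, 20 Hz cutoff at
  500 Hz sampling, applied centered (zero net phase shift) with
  edge-replication padding and taps normalized to exact unit DC gain.
  20 Hz preserves pulse morphology (fundamental plus ~15 harmonics at
  rest) while removing the injected noise band. Like any windowed-sinc
  design the passband is flat only to ~0.1% in the 0.5–2 Hz region, so
  repeated filtering is idempotent to 1e-6 only for near-DC content.
* **Beat segmentation**: feet are pressure minima immediately preceding
  maximal-upslope points (first-derivative peaks) with a 0.3 s refractory
  period; incomplete trailing beats are discarded.
* **Landmarks**: A = foot, C = beat maximum, B = first rising-limb sample
  at or above the A–C amplitude midpoint (the *amplitude* midpoint, per
  the half-rise convention, not the temporal one), D = first second-
  derivative sign change (− to +) after C. The second derivative is
  estimated by central differences after a 5-sample moving average, which
  suppresses spurious zero crossings at 500 Hz without displacing the
  crossing (symmetric kernel). Beats with no crossing before the next
  foot are excluded (`no_inflection`); with several crossings, only the
  first is kept. Indices are 1-based and segments closed (foot to next
  foot inclusive), the idiomatic R convention.

## The 54-feature catalogue

Phases are delimited by the landmarks: `sys_rise` (A→C), `sys_dec`
(C→D), `sys` (A→D), `dec` (C→A′), `dia` (D→A′) and the full beat
(A→A′). The registry partitions into 7 individual features (pressures,
pulse pressure, peak-to-peak interval, heart rate, the inflection ratio
SI = (P(D)−P(A))/PP), 6 durations (including HRIP = t(D)−t(B)),
5 phase-average pressures, 5 trapezoidal areas, 10 normalized areas
(each area divided by its phase sample count and by the beat sample
count), 18 NODIA features (areas, averages and phase-normalized areas
recomputed after subtracting the inflection-point pressure, over the six
phases), and 3 average slopes. `feature_registry()` is the single source
of truth — names, categories, units and formula sketches — so a corrected
formula swaps in without touching the pipeline. SI's expansion is not
standardized in the source literature; we define it as the inflection
ratio above. `dec` (peak to next foot) is kept distinct from `sys_dec`
(peak to inflection) so that both area families exist under distinct
names.

## MRMR ranking

Relevance is the plug-in mutual information between a feature and the CRM
label on a joint histogram; redundancy is the mean MI with
already-selected features; greedy forward selection maximizes
relevance − redundancy (difference scheme; a quotient scheme is
available). Binning is equal-frequency via ranks,
`bins = ceiling(sqrt(n))` capped at 64, which makes the ranking exactly
invariant under strictly monotone transforms of any feature and
well-defined for constant vectors (single bin, MI 0). Ties break by
registry order so rankings are reproducible to the byte.

## Models and evaluation

Six families: ordinary least squares; fine/medium/coarse regression trees
with minimum leaf sizes 4/12/36 (the conventional presets behind those
names); bootstrap-aggregated trees and least-squares gradient boosting,
both with leaf size 8 and 30 learners, boosting with learning rate 0.1
and depth-4 base learners. Trees grow with complexity penalty 0 so the
leaf-size constraint is the capacity control, mirroring toolbox behavior.
Predictions are raw regression output by default — over- and undershoot
of the 0–1 range is informative — with optional clamping.

Two metric families are reported everywhere. The *perfect* (identity-
line) metrics treat y = x as the model: P-RMSE is the RMS residual about
the identity and P-R² = 1 − SSE/SST can be negative. The conventional
metrics fit predicted on calculated CRM by least squares and report the
fitted slope, intercept, squared Pearson correlation and residual RMSE.
P-R² ≤ R² always (the fitted line cannot lose to a fixed line); the two
families agree exactly when the fit is the identity. We regress predicted
on calculated CRM (the orientation is a config switch recorded in every
report). Test metrics pool beats within a test group; per-subject
averaging is available as an option.

## Experiment runner and problem sizes

`run_experiment()` reproduces the study-style artifacts on synthetic
data: the model × top-{15, 10, 5, 1} grid of train/test identity-line
metrics, per-subgroup metrics of the down-selected operating model
(bagged trees, top 10 features), per-group MRMR rankings with rank-shift
annotations against the all-step ranking, and the full train-group ×
test-group metric matrix. Reports are stamped with a config hash and the
seed; identical configs give byte-identical reports.

The default configuration is the full study geometry: 12 subjects per
group in groups 4–8, split 8 training / 4 blind-test at the subject
level, 5-minute steps at 500 Hz. The test suite and the acceptance
script run the same cohort geometry with steps shortened to 30 s and
60 s respectively: per-beat feature distributions within a step are
stationary by construction, so longer steps only replicate near-identical
beats without changing what the models can learn; the shorter steps keep
a full five-seed replication affordable. This choice is stated here once
and used consistently.

## Known limitations

* Synthetic validation only: the generator's monotone links are cleaner
  than human physiology, so absolute metric values on synthetic cohorts
  overstate what restricted clinical data would yield; structural
  conclusions (feature rankings, model ordering, subgroup variability)
  are the meaningful outputs.
* The exact feature formulas of the source catalogue are reconstructed
  from category descriptions and feature names; the registry is designed
  to be swappable if authoritative definitions become available.
* No artifact rejection beyond the landmark validity rules; real-device
  preprocessing would need motion/arrhythmia handling.
* Tree-split behavior follows `rpart`; other toolboxes' trees may split
  differently on tied criteria, so cross-toolbox equality is not claimed.
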