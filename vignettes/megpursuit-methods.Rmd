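---
title: "Models and methods behind megpursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind megpursuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`megpursuit` simulates and analyzes an MEG pursuit-decoding experiment:
can a linear decoder trained to reconstruct a moving target's kinematics
from cortical currents under one task condition (control fixation, covert
attentional pursuit, overt smooth pursuit at 0.5 or 0.8 Hz) reconstruct
them under another? This vignette documents the generative model, the
estimation and decoding machinery, the parameters that matter, and the
design decisions taken where more than one reasonable choice existed.

## The stimulus and task model

The pursuit target moves horizontally as `x(t) = A sin(2π f t)` with the
amplitude tied to a fixed peak velocity: `A = v_peak / (2π f)`. With the
20 deg/s peak velocity used throughout, the 0.5 Hz and 0.8 Hz targets have
peak amplitudes of 6.37 and 3.98 degrees. The sinusoid's starting phase is
not an observable of the analysis; we start at phase 0 (target at the
centre, moving at peak velocity), configurable through
`make_target_trajectory(phase = )`. Trials present a fixation stimulus for
2 s, the stationary target for a further 2 ± 0.5 s (uniform jitter), and
4 s of motion; sensor epochs span −0.4 to 4.0 s around motion onset. At the
raw 1000 Hz rate an epoch holds 4401 samples with onset at sample 401
(epoched grids include the motion-offset endpoint).

The task model assumes three computational functions — visual
information-processing, maintenance of attention, eye-movement control —
required cumulatively by the control, covert, and overt conditions
(`task_functions()`).

## What the generator emulates

`simulate_dataset()` produces the whole synthetic recording:

* **Source space.** Dipoles on a sphere-like shell (radius 80 mm, 2%
  radial jitter) in contiguous region patches: PreCC, MSFC, LOTC, IPC,
  precuneus, V1/V2 and a task-irrelevant remainder (fractions 8/6/10/10/6/
  12/48%). Orientations are random unit vectors standing in for surface
  normals. Desk-scale default: 500 dipoles (the reference dense grid of
  ~20,000 is reachable through configuration, not needed for testing the
  chain).
* **Subpopulations.** Three index sets: visual (V1/V2 + LOTC), attention
  (IPC, precuneus, MSFC, PreCC), and eye movement — deliberately occupying
  *different dipoles of the same fronto-parietal regions* than attention,
  concentrated in PreCC. This is the generative hypothesis the analysis is
  meant to detect: shared regions, distinct subpopulations.
* **Encoding.** Each active population's current is
  `amp · gain(task) · (0.8 · pos_n(t − lag) + 0.6 · vel_n(t − lag))`
  per dipole (kinematics normalized to unit peak; per-dipole weights
  U(0.5, 1.5); `amp` = 40 pA·m/mm² per unit gain, placing active currents
  in the 25–250 pA·m/mm² range reported for physiological current
  densities). All populations share this encoding and a −100 ms lag
  (currents lead the target, consistent with predictive pursuit control
  and with time-lag analyses placing the optimum between −50 and −250 ms).
  A Gaussian evoked transient (amplitude 30, centre 0.1 s, width 30 ms)
  hits the visual population at motion onset; white background noise
  (SD 10) covers every dipole.
* **Task gains.** Visual gain 1 in every task; attention gain 1 in covert;
  eye-movement gain 2 in overt only (matching the roughly two-fold
  overt/covert current-density contrast in precentral cortex). Under overt
  pursuit the visual and attention gains are damped to 0.3: successful
  pursuit stabilizes the target near the fovea, so the retinal-slip drive
  of visual motion responses shrinks, and the strong oculomotor drive
  supplants much of the sustained top-down attention signal. These
  multipliers were calibrated once, while designing the generator, so that
  overt-task currents are dominated by the eye-movement population — the
  structure the study's generalization argument hinges on — and were then
  frozen.
* **Artifacts.** Two ocular sources and one cardiac source, three
  orthogonal dipoles each (nine extra-brain currents). In overt tasks the
  horizontal ocular components track the target with a 50 ms latency and
  0.3° tracking noise; under fixation they carry fast low-amplitude jitter
  (~0.4° SD). Blinks are Gaussian transients on the vertical components at
  0.2 Hz; the cardiac source fires a 50 ms-wide pulse train at 1.1 Hz. The
  ocular gain (60 units/degree) makes the artifact a first-order
  contaminant of overt sensor data, which is the condition the
  artifact-aware inverse exists to handle.
* **Forward model.** Gains are the dipole orientation projected on the
  source-to-sensor direction with inverse-square distance decay, plus 5%
  multiplicative calibration jitter; 64 sensors on a helmet-like cap. This
  is a deliberately abstract stand-in for a boundary-element head model —
  adequate for exercising the inverse/decoding chain, and swappable.
* **Trial rejection.** Trials whose sensor values exceed 95% of a
  configurable recordable range are flagged (`reject_trials`), mirroring
  standard amplitude-based artifact rejection.

What the generator does *not* emulate: head-conductivity geometry, sensor
calibration error structure, realistic EOG/ECG waveshapes, microsaccades,
inter-subject anatomical variability. Passing tests therefore show that
the *chain* behaves correctly under its own generative assumptions, not
that those assumptions exhaust real MEG data.

## Source estimation

`preprocess()` detrends each channel linearly (the synthetic system has no
reference array for DC-drift removal, so detrending replaces it), applies
a nine-period centred moving average at the raw rate (reflection padding
at the edges), and decimates to 200 Hz — 881 samples per epoch with onset
kept on the grid.

Estimation works on reduced currents: every fourth dipole is a reduced
dipole (the reference ratio, 20,004 → 5004 ≈ 4:1), and cortical currents
are `J = W Z` with Gaussian, unit-sum columns of `W` (width σ defaults to
twice the median nearest-neighbour distance; the reference analysis states
a Gaussian weighting without a width). The observation model is

`B = [Ĝ, G_extra] [Z; J_extra] + ε`,  `Ĝ = G W`,

with independent zero-mean Gaussian priors per source and gamma
hyperpriors on the source precisions (shape 0.01 — weakly informative —
with prior variance scaled to the data and magnified 100× for the
extra-brain sources, which are expected to dwarf cortical currents, and by
the region prior inside functionally active regions, default 10×). Noise
precision carries a flat gamma prior. Inference is mean-field variational
Bayes with exact coordinate updates, so the evidence lower bound is
non-decreasing — an invariant the tests assert. Convergence: relative
objective change < 1e−6 or 200 iterations; non-convergence warns and flags
rather than fails. With hyperparameter updates disabled, the posterior
mean is exactly the Tikhonov-regularized solution, which the tests check
against the closed form.

Hyperparameters are updated on trials pooled within a task (the per-task
current statistics are what differ by design); posterior means are
returned per trial, since the decoder consumes single trials. The
published description of this estimator does not include update equations,
so this implementation is behaviourally — not numerically — faithful: it
reproduces simultaneous cortical + extra-brain estimation under an
fMRI-informed variance prior, and its ablation (`with_extra = FALSE`)
demonstrably increases eye-artifact leakage into posterior cortical
estimates. Because in overt trials the artifact shares the target's
waveform with genuine visual responses, leakage is measured as the
*partial* correlation between region-mean estimated currents and the
ocular current, given the target trajectory.

## The decoder

`fit_slir()` regresses the target's position (and, separately, velocity)
on lagged copies of every input dipole's current: lags
`tpred + tau·j, j = 0…dtau` in samples of the 200 Hz grid, defaults
(1 + 6j) — eleven taps from 5 to 305 ms before the predicted sample. The
published parameter table labels the lag spacing in milliseconds, but its
own window arithmetic (−305 to −5 ms from eleven taps at 200 Hz) works
only in samples; we implement samples, which reproduces the printed window
exactly.

Sparsity acts on space only: all taps of a dipole share one relevance
hyperparameter (grouped automatic relevance determination), so a dipole's
eleven weights are kept or pruned together. Fitting is evidence
maximization with gamma hyperpriors on the group precisions. The hyperprior
shape defaults to 1 (an exponential-type prior on each precision): plain
type-II maximum likelihood retains a substantial fraction of chance-level
inputs (a group of correlated taps can raise the evidence slightly even
when pure noise), whereas the unit-shape prior drives such groups'
variances to collapse. Groups whose prior variance falls below 1e−8 times
the largest group's are hard-zeroed and removed. With relevance updates
disabled the fit is exactly ridge regression (tested against the closed
form). Position and velocity are independent models with separate
relevances, since selected-dipole counts are reported per regressand.

Inputs are z-scored per dipole with parameters learned on the training
trials only; the standardization is absorbed into the returned weights so
prediction operates on raw currents. Fitting uses accumulated sufficient
statistics (per-trial crossproducts), which makes cross-validation refits
cheap and is exactly equivalent to fitting the concatenated design.

## Evaluation machinery

Same-task accuracy uses k-fold cross-validation over trials (ten folds at
full scale); cross-task cells train on all trials of one task and test on
all trials of the other. Correlation (shape only, affine-invariant) and
determination coefficients (`1 − SSE/SST`, amplitude-sensitive, unbounded
below) are computed per test trial and averaged — the reference analysis
plots trial-averaged predictions without stating the aggregation, and a
concatenated-series alternative would mix trial boundaries into the
statistic. Normalized scores divide each cell by the same-task score; the
sentence defining the normalization admits either diagonal, so the test
task's own diagonal (the achievable ceiling on that test set) is the
default and the train-task diagonal is available (`mode = "train"`).
Position and velocity are pooled (averaged within replicate) for
summary-table classification: high ≥ 0.6, middle ≥ 0.2, low < 0.2.

Significance uses a trial-permutation test: the null permutes the
trial correspondence between predicted and true series and circularly
shifts each prediction by a random offset,
`p = (1 + #{null ≥ observed}) / (1 + n_perm)`. Shuffling alone cannot form
a null here because the true series is the same target in every trial; the
circular shift is what destroys time-locking while preserving each
series' autocorrelation. The test is exact for cyclically stationary
predictions and mildly conservative otherwise (the wrap point breaks
strict invariance); the calibration suite verifies nominal size under a
shift-invariant null. Families of cells are corrected with
Benjamini–Hochberg (`p.adjust`, cross-checked against a brute-force
step-up in the tests).

Shared-dipole categorization assigns every selected dipole to exactly one
category (exclusive per task, covert-shared, overt-shared, same-frequency
shared, shared by ≥ 3 tasks); two-task combinations involving the control
task have no named category in the reference figure, so a residual
two-task category makes the fractions sum to 1.

The lag sweep refits a single-tap decoder with currents shifted relative
to the target (negative lags = currents precede the target) and reports
the correlation profile and argmax; a single tap is used because a
multi-tap model can synthesize arbitrary phase shifts from a sinusoidal
regressor, flattening the profile.

## Group statistics

`rb_anova1` / `rb_anova2` are within-subject (randomized-block) ANOVAs:
each effect is tested against its own interaction with the block factor,
giving df (a−1, (a−1)(n−1)) for a levels and n blocks — (4, 20) for five
tasks and six subjects, and (16, 80) for the 5×5 interaction. They wrap
`aov()` with error strata and are verified against explicit
sum-of-squares decompositions. Tukey HSD uses the studentized range
(`ptukey`) with the effect's own error mean square, consistent with the
within-subject error convention; simple main effects re-run the one-way
block ANOVA within each level of the fixed factor (no additional
correction across levels is applied — whether the original analysis did
is unstated). Sphericity corrections are deliberately out of scope.

## Problem sizes, tolerances and degenerate inputs

The package's own test and demonstration runs use deliberate desk scales,
chosen as the smallest sizes at which every qualitative property of the
full design is expressed: 500 dipoles / 64 sensors / 4 trials per task for
the sensor-level inverse studies; 120-dipole spaces, 8–10 trials per task,
100 Hz current grids and 4–5-fold cross-validation for the
decoder-generalization replicate studies (20 seeded replicates); 2000-row
lagged designs for the support-recovery fixtures. Closed-form oracle
comparisons use 1e−6 relative tolerance; sum-of-squares identities 1e−9.
Degenerate inputs are handled explicitly: a constant regressand returns an
intercept-only decoder; constant responses give F = 0, p = 1; zero
same-task scores exclude that replicate from normalization with a warning;
all-zero sensor data yield (numerically) zero current estimates.

## Known limitations

* The forward model is not a conductor-geometry head model; absolute
  sensor units are arbitrary, so current-density recovery is assessed in
  correlation, not amplitude.
* The inverse is a generic hierarchical variational estimator, not a
  numerical re-implementation of any specific published code.
* Sensor coverage (a superior cap) leaves inferior patches of the
  spherical source shell poorly observed; region-level statistics at small
  source counts are noisy, which is why regional contrasts are tested at
  the 500-dipole scale.
* Cross-frequency generalization in the synthetic world is governed by
  amplitude ratios of the two targets; real cross-frequency transfer
  involves temporal dynamics the linear encoding does not model.
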