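---
title: "Joint EEG-fMRI analysis of music-induced affect: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint EEG-fMRI analysis of music-induced affect: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affectfuse)
```

## The scientific problem

Prefrontal EEG asymmetry — the difference between left and right
prefrontal band power — tracks the approach-withdrawal (valence) axis of
emotional experience: under the hemispheric valence hypothesis, positive
valence shifts the balance toward the left hemisphere. fMRI, meanwhile,
localises affect-related activity to a sub-cortical network (amygdala,
cingulate, auditory cortex, cerebellum) that EEG cannot see directly.
`affectfuse` implements a complete EEG-informed-fMRI pipeline for a
paradigm in which participants listen to 40-second music excerpts, each
targeting one region of the valence-arousal circumplex for 20 s and a
different region for the next 20 s, while continuously reporting their
felt affect with a joystick. Three trial types separate affect from the
act of reporting:

* **music only** — listening, no joystick;
* **music + reporting** — listening and continuous reporting;
* **reporting only** — no music; the participant re-tracks the replayed
  joystick record of an earlier music + reporting trial of the same
  excerpt. This is the movement and visual-attention control.

Every reporting-only trial is preceded, somewhere earlier in the
session, by the music + reporting trial of the same excerpt; reports
from music + reporting trials are copied into the matching music-only
trials for analysis.

The pipeline has four inferential stages:

1. **Behaviour.** Reports are cut into 20-s sub-trials and the per
   sub-trial mean is correlated (Pearson) with the targeted circumplex
   value. The axes of the circumplex are treated as approximately
   linear, which is why Pearson rather than a rank correlation is used.
2. **EEG.** After common-average referencing and a zero-phase 1-45 Hz
   third-order Butterworth filter, Laplacian derivations are taken at F3
   (references FP1, F7, Fz, C3) and F4 (references FP2, F8, Fz, C4);
   windowed mean-square band power is computed in delta (0-4 Hz, with
   the 1 Hz high-pass this is effectively 1-4 Hz), theta (4-8), alpha
   (8-12) and beta (13-20) Hz; and the asymmetry series is the
   left-minus-right power difference. Per-trial mean asymmetry is
   compared between high- and low-valence trials with two-sample
   Kolmogorov-Smirnov tests, Holm-Bonferroni corrected across bands.
3. **fMRI.** A mass-univariate GLM written from first principles:
   regressors are convolved with the canonical double-gamma HRF (peak
   delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio
   6, 32-s support, peak-normalised), entered with a movement confound
   and a Legendre-polynomial drift basis, fitted by OLS per voxel, and
   tested with extra-sum-of-squares F contrasts. Family-wise error is
   controlled by Bonferroni (default) or by a Freedman-Lane max-F
   permutation scheme. Affect-related voxels are isolated with the
   exclusion contrast `C = A \ B`, where A is the FWE-significant set
   for the regressor of interest over music trials and B is the set
   co-varying with the reporting task alone.
4. **Fusion.** The asymmetry series (or the Shannon entropy of its
   dynamics) is co-registered to the scanner clock, anti-alias filtered,
   down-sampled to the volume rate (0.5 Hz at TR = 2 s), HRF-convolved
   and used as the explanatory variable in the same GLM machinery.

## Shannon entropy of asymmetry dynamics

Disorder of the asymmetry series within a trial is measured by the
Shannon entropy `H = -sum(P log2 P)` (with `0 log 0 := 0`) of the
discretised asymmetry values; larger H means the asymmetry wandered over
more states, i.e. was less predictable. Discretising a continuous
series involves two free choices, and both matter:

* **Bin count.** 16 equal-width bins by default. Entropy analyses use a
  shorter band-power window (1 s) and a finer step (0.25 s) than the
  fusion chain, so a 40-s trial contributes ~160 power samples — enough
  for a stable 16-bin histogram.
* **Bin edges.** `trial_entropy()` defaults to a *common state
  alphabet*: the bins span the pooled range of asymmetry over all music
  trials, so every trial is scored against the same set of states and H
  directly reflects how many of those states a trial visits. The
  per-trial auto-ranged alternative (`edges = "per_trial"`) is
  scale-invariant: it sees only the *shape* of a trial's occupancy, not
  its extent, and in simulation it is nearly blind to genuine
  between-trial differences in asymmetry disorder because heavy-tailed
  band-power noise stretches each trial's own range. The common
  alphabet is therefore the default for trial comparisons.

For the fusion GLM the per-trial entropies are embedded as a boxcar that
carries, by default, the *centred* entropy (trial entropy minus the
across-trial mean) during each music trial and 0 elsewhere. The raw
embedding is dominated by the music-on/off structure of the session and
aliases the task boxcar — with it, every entropy-coupled voxel also
co-varies with the reporting-only indicator and is swallowed by set B.
Centring leaves exactly the entropy modulation.

## The synthetic-data generator

The package ships a
seeded generator (`simulate_dataset()`) that emulates the statistical
structure the analysis assumes, with ground truth for recovery testing.

**Affect.** Latent valence/arousal are the attenuated circumplex target
(`target_gain`, default 0.122) plus an AR(1) wander (marginal SD 0.3,
correlation time 5 s — smooth, drifting traces). Most of the wander
(`stim_frac = 0.95`) is stimulus-locked: the same excerpt evokes nearly
the same trajectory at every presentation. That is the premise that
licenses copying reports into music-only trials, and the generator makes
it concretely true. The reported trace is a first-order lag follower
(time constant `report_lag = 1` s) of the latent state during
music + reporting trials, a copy of that record during music-only
trials, a noisy re-tracking of the replay during reporting-only trials,
and a relaxation to neutral between trials; everything is clipped to
[-1, 1]. `target_gain` is calibrated by simulation so that the pooled
sub-trial target-report correlation is near r = 0.3 — music only
loosely steers felt affect.

**EEG.** Each channel mixes band-limited Gaussian oscillations (delta /
theta / alpha / beta, RMS 2 / 1.5 / 2 / 1.2 uV) with white noise
(SD 1 uV). Homologous left/right pairs share a large bilateral component
(`eeg_shared_frac = 0.9`). The shared prefrontal alpha and beta
component is amplitude-modulated antisymmetrically:
`(1 + g m(t))` on the left, `(1 - g m(t))` on the right, with
`g = eeg_valence_gain = 0.6` and `m(t)` following latent valence — so
left-minus-right Laplacian band power grows linearly with valence.
Within each trial `m(t)` additionally carries a slow, demeaned linear
drift of the operating point whose amplitude grows steeply as the
trial's valence falls (`entropy_mod = 3`, logistic in valence with scale
`valence_scale = 0.07`). A drifting operating point spreads the
asymmetry's state occupancy — the maximally disordered, uniform
histogram — without moving the trial mean, so low-valence trials have
higher asymmetry entropy while the mean-asymmetry effect stays clean.

**BOLD.** An abstract 12-cubed voxel grid at 3 mm isotropic resolution
(no anatomy; localisation claims are out of scope). Disjoint 2-cubed
ROIs are driven by the HRF-convolved, standardised valence, arousal,
asymmetry-regressor, entropy-regressor, or reporting-movement boxcar
time courses; a null ROI (amplitude 0) is always kept for type-I-error
checks. Null voxels carry only a Legendre drift (order 3, random
coefficients, SD 0.3) and white noise (SD 1) over a baseline of 100.
The movement driver is a per-trial boxcar over music + reporting and
reporting-only trials — the minimal surrogate of joystick use.

**What the generator does not emulate:** volume conduction and realistic
EEG forward physics, scanner and ballistocardiogram artifacts, head
motion, anatomical structure, autocorrelated (AR) BOLD noise, and
between-participant random effects. Passing recovery tests therefore
demonstrate the *statistical* correctness of the pipeline under its own
assumptions, not robustness to real-data artifacts.

## Design choices in the analysis

* **Order of operations** (CAR, broadband filter, Laplacian, band
  filter, windowed power, asymmetry) is fixed; Laplacian and band
  filtering only commute approximately, and a single order makes runs
  reproducible.
* **Power, not amplitude**: asymmetry is a difference of mean-squared
  amplitudes (uV^2). An amplitude variant can be obtained by taking
  square roots of the power series before differencing, but power is
  the default because the feature is defined as band-power activity.
* **Zero-phase filtering** (forward-backward, effective order 6)
  avoids group delay misaligning EEG features against the scanner
  clock.
* **Set B from the reporting-only indicator.** B is the FWE-significant
  set of an F-test on the HRF-convolved reporting-only boxcar. The
  joystick trajectory itself would be an alternative regressor; the
  boxcar is its minimal surrogate and matches the generator's movement
  driver.
* **Movement confound enters convolved.** The haemodynamic response to
  joystick use is what contaminates music-trial BOLD, so the confound
  column is the HRF-convolved task indicator.
* **Bonferroni as the FWE default.** Random-field corrections need
  smoothness estimation that is meaningless on a small abstract grid;
  Bonferroni and the Freedman-Lane max-F permutation both control FWE,
  which is the property the analysis claims. Alpha is always an
  explicit argument: affect maps are conventionally thresholded at
  0.05 and EEG-informed maps at 0.01, and silently defaulting one
  invites mistakes.
* **Legendre drift** (default order 3) rather than a cosine basis:
  the simplest orthogonal family; configurable.
* **26-connectivity** for clusters, 6-connectivity available.
* **Band selection for fusion is data driven**: `run_fusion_study()`
  fuses the bands in which the KS + Holm battery rejects, with an
  explicit override to force specific bands.
* **Tie rule**: a trial whose mean reported valence equals the
  threshold is labelled low.
* **Analyses are single level.** Replicate simulated datasets play the
  role of participants; the design matrix accepts arbitrary confound
  columns, so concatenated runs with run-wise intercepts can be built,
  but no random-effects machinery is provided.

## Calibration studies and problem sizes

The packaged calibration studies (also exercised by the test suite and
`scripts/acceptance.R`) use sizes chosen to make Monte-Carlo error
small while keeping a full run comfortably on a laptop:

* `run_null_study()`: 15 trials, a 7-cubed grid, 100 Hz EEG. Across 500
  replicates the Bonferroni-thresholded fusion chain's family-wise
  error sits inside the binomial band around 0.05, per-voxel p-values
  are uniform, and the KS + Holm battery's family-wise error stays at
  or below its nominal level (the asymptotic KS p-value is
  conservative at 5 + 5 trials per split).
* `run_recovery_study()`: 18 trials, a 10-cubed grid, all couplings
  active. `calibrate_coupling()` solves for each ROI amplitude such
  that the *detecting* analysis has 95% theoretical per-voxel power at
  its Bonferroni-corrected level — the noncentrality is computed from
  the actual analysis regressor residualised against the rest of the
  design, projected onto the generator's true signal time course.
* `directional_consistency()`: 75 trials (50 music-listening). Trials
  are ordered by mean reported valence and extreme pairs are compared;
  the success counts are one-sided sign tests.
* The behavioural correlation pools 21 simulated participants of 36
  trials each, mirroring the scale at which such studies report
  behavioural couplings.

## Known limitations

* The entropy contrast depends on the common-alphabet discretisation;
  with per-trial auto edges the effect shrinks drastically (see above).
* The asymptotic KS p-value is conservative for very small groups;
  batteries on fewer than ~10 trials per condition lose power.
* BOLD noise is white; with strongly autocorrelated noise the OLS
  p-values would need pre-whitening, which is not implemented.
* EDF input is not supported; EEG I/O uses labelled delimited text.
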