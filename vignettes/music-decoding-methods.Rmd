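---
title: "Decoding heard music from EEG with fMRI-informed source analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding heard music from EEG with fMRI-informed source analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the pipeline

`musedecode` implements an end-to-end pipeline for reconstructing the music a
listener heard from multichannel scalp EEG, using a statistical map from
simultaneously acquired fMRI to decide *where* in the brain the EEG source
analysis should look. The stages are:

1. **Experiment simulation** — monophonic piano-like stimuli, a trial
   schedule, forward-modelled EEG and a BOLD-like 4D volume with planted
   music-responsive clusters, so every downstream stage can be tested
   without access to recorded human data.
2. **GLM T-contrast** (music vs no-music) on the volume, then **greedy
   minimum-distance selection** of dipole locations from the T-map.
3. **SOBI** blind source separation of the EEG and per-component
   back-projection.
4. **eLORETA** source estimation at the selected dipoles for each component
   projection, concatenated into a `(dipoles x components) x samples`
   feature matrix (124 rows for 4 dipoles and 31 channels).
5. A **bidirectional LSTM** regressor mapping features (downsampled
   1000 to 100 Hz) to the music waveform, trained in a run-wise
   cross-fold scheme — each run serves once as the held-out test set.
6. **Evaluation**: time/frequency Pearson correlations, spectrogram
   structural similarity (SSIM), a 4000-resample bootstrap null from trial
   shuffling, rank-accuracy identification of the heard piece, a
   permutation test on the mean rank accuracy, and a tempo-confound
   analysis.

A single call runs everything:

```{r}
library(musedecode)
res <- run_pipeline(pipeline_config(seed = 20), "artifacts")
print(res)
```

# The synthetic experiment

The generator's default experiment is: 36 pieces of
40 s monophonic music targeting the 9 combinations of low/neutral/high
valence and arousal (4 pieces per combination), played over 3 runs of 12
trials. Each trial is preceded by a uniformly drawn 1–3 s fixation and
followed by a 0.5 s break. Two trial types carry music (listening only, and
listening while continuously reporting felt affect); a third,
reporting-only, type carries none and provides the GLM's no-music
condition. The default per-run mix is 5/4/3, so 27 of the 36 trials carry
music and every piece is heard at most once. Affect targets are metadata
only: nothing in the simulated neural signal depends on them, because the
decoder never uses the affect dimension.

**Music model.** A piece is a train of note onsets at a per-piece tempo
drawn uniformly from 60–180 bpm, with Gaussian onset jitter (sd 4 % of the
beat; a parameter, so an exact metronome is available). Each note is an
exponentially decaying envelope (decay 0.25–0.45 s) carrying a sinusoidal
fundamental between 1 and 30 Hz around a per-piece register. Real piano
spectra live far above this band; the register is deliberately low so that
the decoding target — the waveform after downsampling to 100 Hz — retains
its content. This is the main idealisation of the generator.

**EEG coupling.** Cortical sources at the "active" dipoles follow the
amplitude envelope of the playing piece (rectified waveform, low-passed at
8 Hz, lagged 100 ms), the established envelope-tracking regime of
auditory EEG. Sources are projected to 31 sensors through the spherical
leadfield with radial orientations; every source also carries 1/f noise
(sd 0.02 in source units, about a sixth of the envelope drive), 20
background grid sources carry 1/f noise only, and white sensor noise
(sd 1e-5, the median projected signal scale of the default head model) is
added. These defaults give a best-channel envelope correlation around
0.85 — a strongly coupled, low-noise recording, which is the regime the
end-to-end recovery checks are defined for. What passing those checks shows
is that the pipeline's machinery is correct, not that real EEG (with
ocular/muscle artifacts, non-stationarity, far weaker coupling) would give
similar numbers.

**BOLD model.** Voxel time series are white noise plus, inside spheres
around the planted centres, the music boxcar convolved with a canonical
double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6) sampled at
TR = 2 s.

# Head model

The head model is an analytic three-shell concentric-sphere conductor (brain/skull/scalp radii
80/85/92 mm, conductivities 0.33/0.01/0.43 S/m) — the standard compromise that
individual-anatomy finite-element models refine: CSF and white matter are
absorbed into the brain shell, and no MRI segmentation is needed. The scalp potential is evaluated by a Legendre series
(100 terms); per harmonic degree the interface conditions give a small
linear system solved once, with radii normalised to the scalp radius for
conditioning. Dipoles sit on a regular grid (15 mm spacing) strictly inside the brain
shell; a grid point at
the exact centre has no defined tangential field and is dropped. Gains are
average-referenced, so columns sum to zero. The degenerate equal-
conductivity case is verified in the tests against a closed-form
homogeneous-sphere solution derived independently via generating
functions, to 0.1 %.

# Dipole selection

The per-voxel OLS fit uses one music and one no-music regressor (HRF-
convolved boxcars) plus per-run intercept and linear drift; the T statistic
tests music minus no-music. Family-wise control is Bonferroni by default —
a stand-in for random-field FWE, which is out of scope — and an
uncorrected threshold is available for exploratory maps. Selection is
greedy: pop
the largest-T candidate, keep it only if its distance to every kept
location strictly exceeds m = 30 mm, stop at n_l = 4. Ties in T are broken
by the lowest voxel index so the output is reproducible; distances are in
mm between voxel centres.

# SOBI and eLORETA

SOBI here is the standard second-order-statistics algorithm: whiten, then jointly diagonalise symmetrised lagged covariances
(default lags 1–100 samples) by Jacobi rotations, stopping when the largest
rotation angle falls below 1e-8 or after 200 sweeps. The algorithm has no
random element. Artifact rejection is an explicit component list (plus
optional kurtosis and mains-power heuristics), never interactive; the
default rejects nothing, which is also what the 124-row feature matrix
arithmetic requires (M = 31 components retained).

eLORETA iterates the 3x3 block weights to their fixed point
(tolerance 1e-6, at most 100 iterations; non-convergence is a warning and
is recorded on the operator). The regulariser is `alpha` times the
trace-normalised sensor gram with average-reference centering;
`alpha = 0.05` by default, small enough that the zero-localisation-error
property is exercised at `alpha = 1e-3` in the tests. One time course per
dipole is obtained by projecting the three orientation moments onto the
principal orientation; free orientation with principal-axis reduction is the design choice here
(fixed-orientation alternatives would need anatomical priors the sphere
model cannot supply). For the per-component feature blocks the orientation is fixed
once from the full reconstruction, which makes the blocks sum exactly to
the full-data source estimate. An LCMV beamformer is available behind the same operator interface;
eLORETA is the default because its zero-localisation-error property is
what the fMRI-informed dipole selection relies on. Features are computed
at the acquisition rate and downsampled afterwards.

# Decoder

The experiment-scale architecture is four stacked biLSTM layers of 250
units per direction with a linear read-out (`full_decoder_spec()`). The
package's working default is a desk-scale variant — one layer, 32 units —
which trains in about half a minute per fold on one CPU at the full 27
music trials; the tests and the end-to-end check use it. Training
hyperparameters are package choices: Adam at 1e-3, global gradient-norm
clipping at 1.0, 15 epochs, and chunked backpropagation through 10 s
windows. Targets are z-scored per run
at training time — a numerical convenience; evaluation z-scores both
series again, so the measured similarities are scale-free either way.
Feature rows are z-scored per run for the same reason. Weight
initialisation and data order are fixed by the decoder-spec seed, and the C++ core
contains no RNG, so training is bit-reproducible on one CPU thread.

A fold whose loss becomes non-finite is aborted with a warning and its
trials are skipped, the per-fold analogue of excluding a non-converging
subject from a group analysis.

# Evaluation

Per-trial similarity uses three measures: Pearson correlation of the
100 Hz series, Pearson correlation of Welch power spectra (1 s Hann
segments, 50 % overlap; power rather than amplitude spectra — both the
resolution and that choice are package defaults), and SSIM between
log-power spectrograms. The spectrogram is an
STFT with 1 s Hann window, 50 % overlap, frequencies 0–50 Hz; each
comparison pair is min–max normalised to a shared [0, 1] range; SSIM uses
the conventional K1 = 0.01, K2 = 0.03 and an 11-bin Gaussian window of
sd 1.5 — the field's standard SSIM settings.

Significance of each mean similarity comes from a bootstrap null built by
shuffling which reconstruction is paired with which original (4000
resamples), with `p = (1 + #[null >= observed]) / (n + 1)`.

For identification, both series sets are z-scored and band-pass filtered
0.035–4.75 Hz. A 0.035 Hz high-pass cannot be realised inside a 40 s
segment, so the zero-phase 4th-order Butterworth filter is applied to the
continuous concatenated series before segmentation. Spectrogram SSIM of
reconstruction k against every original i fills the matrix C; trial k's
comparison set is all other trials carrying a *different* piece (excluding only trial k itself is the other defensible reading; both are
exposed, different-piece is the default, and with unique piece assignment
they coincide). Rank accuracy gives half credit to ties, which preserves the
0.5 null expectation exactly. Significance of the mean rank accuracy is a
permutation test over the trial-to-piece assignment of C (10000
permutations).

Tempo is estimated from envelope-derivative peaks (adaptive threshold,
0.2 s refractory gap): the mean tempo is 60 over the median inter-onset
interval and the range follows from the 10–90 % interval quantiles.
Typicality of a trial's tempo is its Gaussian density under the mean and
sd of all trial tempos. The confound analysis correlates both quantities
with per-trial rank accuracy.

# Numerical choices and degenerate inputs

* Zero-phase filtering pads by odd reflection before `filtfilt` so edge
  transients do not leak into short segments; the decimator is a 96-tap
  FIR normalised to exact unit DC gain, cutoff 0.4 times the new rate.
* Constant series have undefined correlations; they are recorded as
  missing and excluded from means, with a message.
* An exactly reproduced regressor would give an infinite T; |T| is capped
  at 1e6 and p floored at the smallest positive double.
* An empty GLM candidate set yields an empty dipole set with a warning
  (not an error); an exhausted candidate set yields a short set with a
  message.
* Rank-deficient EEG gives a reduced-rank SOBI decomposition with a
  warning; a rank-deficient GLM design is an error naming the collinear
  columns.
* Seeds: every generator is a pure function of its configuration and seed;
  the pipeline derives per-stage seeds from the master seed with a fixed
  integer map kept below 2^31.

# Problem sizes

The default configuration is the full study geometry: 36 pieces x 40 s,
3 runs x 12 trials, 31 channels at 1000 Hz, a 15 mm source grid (618
points), TR 2 s. On one CPU this runs in roughly ten minutes, the bulk
in SOBI's lagged covariances and the three decoder folds. The test suite
uses a 30 mm grid (80 sources) and shorter pieces for module tests, and
the full geometry for the end-to-end recovery check. The eLORETA
localisation property is exercised over all 240 single-dipole truths of
the coarse grid; SOBI separation over ten seeded 5-source AR mixtures of
60 s at 100 Hz.

# Known limitations

* The stimulus register (1–30 Hz fundamentals) is an idealisation forced
  by the 100 Hz decoding rate; nothing about real piano timbre is
  simulated.
* Affect targets do not modulate the simulated signal, so affect-related
  decoding cannot be studied on this generator.
* The spherical head model ignores head-shape and tissue anisotropy;
  conclusions about millimetre-level localisation on real anatomy are out
  of reach.
* MR gradient and ballistocardiogram artifacts are not simulated, and the
  config-driven rejection is a stand-in for expert visual inspection.
* The frequency-domain correlation is high even between mismatched trials
  (all stimuli share the same spectral family), so its bootstrap p-value
  is weak by construction; identification rests on the time-frequency
  SSIM, as in the modelled analysis.
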