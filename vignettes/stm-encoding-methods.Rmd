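---
title: "Modelling neural encoding of spectrotemporal modulations in degraded speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling neural encoding of spectrotemporal modulations in degraded speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmtrf)
```

## The scientific problem

When listeners hear degraded speech, perception depends both on the quality
of the acoustic signal and on what the listener expects to hear. Two broad
families of neural coding schemes make different predictions about how these
factors combine. Under a *sharpening* scheme, prior knowledge suppresses
activity encoding competing interpretations, so the fidelity of the neural
representation of the heard word improves whenever either signal quality or
prior knowledge improves. Under a *prediction-error* scheme, expected
content is subtracted from the bottom-up input and only the residual is
represented; this predicts a diagnostic *interaction*: with uninformative
(mismatching) priors, more sensory detail leaves more unexplained signal and
representations improve, while with accurate (matching) priors, more detail
is explained away more completely and representations get *worse*.

`stmtrf` implements the full computational chain needed to test this
signature with lagged linear (temporal response function, TRF) models of
sensor-level neural recordings: noise-vocoded stimulus construction,
stimulus feature spaces, ridge-regression encoding and decoding with
cross-validation, permutation statistics, and a synthetic-data generator
that produces stimuli and sensor responses with known ground truth so the
whole pipeline is testable without any external recordings.

## Stimulus degradation: noise vocoding

`vocode()` degrades a waveform by dividing 70–5000 Hz into `n` channels
whose boundaries are equally spaced on the Greenwood cochlear-position axis
(`greenwood_bank()`, human parameters A = 165.4, a = 2.1, k = 0.88);
extracting each channel's envelope by half-wave rectification and a
second-order 30 Hz low-pass; imposing that envelope on band-matched white
noise; re-band-limiting; and summing. Output RMS is matched to a reference,
and `rms_equalize()` levels a whole stimulus set. Channel centres use the
midpoint-of-position convention; a published centre list can be imposed via
`centers_override` since centre conventions differ between implementations
by a few percent.

All band-pass and low-pass operations use zero-phase Butterworth-magnitude
filters applied in the frequency domain (the amplitude response of a
forward–backward pass of the named filter, with exactly zero phase). We
chose the spectral implementation over recursive filtering because
transfer-function coefficients of a 4th-order band-pass with edges near
70 Hz at a 44.1 kHz rate are numerically fragile, while the spectral form is
unconditionally stable and keeps envelope timing aligned with the neural
lag axis — a property the lag estimates downstream depend on.

## Feature spaces

All feature spaces are built from the *clear* (pre-vocoding) audio, so any
condition difference in model accuracy reflects neural encoding rather than
stimulus acoustics. They are sampled at 80 Hz (the neural rate):

* **Envelope** (1 feature): sum of the 24 Greenwood-channel envelopes.
* **Spectrogram** (24): the channel envelopes individually; an optional
  compressive exponent (e.g. 0.3) models peripheral compression.
* **Spectral derivative** (24): half-wave-rectified temporal difference of
  the spectrogram (spectral onsets).
* **Spectrotemporal modulations** (25): the auditory spectrogram
  (128 constant-Q channels, log-spaced 180–7040 Hz, 8 ms frames, 8 ms time
  constant, no compression) is filtered by a separable 2D Gabor-type bank —
  log-Gaussian magnitude profiles (sigma 0.5 octave, Q about 1) centred at
  0.5/1/2/4/8 cycles per octave and 1/2/4/8/16 Hz, with quadrant masks
  selecting the up/down sweep directions. The full tensor has
  128 x 5 x 5 x 2 = 6400 dimensions per frame; averaging over frequency
  channels and directions leaves one time series per grid cell.
* **Phonetic features** (13): Voiced, Unvoiced, Bilabial,
  Labiodental/Dental, Alveolar, Velar, Plosive, Nasal, Fricative, Liquid,
  Front, Central, Back, held between successive phoneme onsets; diphthongs
  and affricates carry the mean of their component vectors. The
  phoneme-to-feature map ships as an editable CSV.

`combine_spaces()` concatenates spaces (24+13 = 37, 24+24 = 48 columns) and
records the column blocks for banded ridge. `prepare()` z-scores acoustic
spaces per trial (each series to mean 0, SD 1; categorical phonetic columns
are left untouched; constant columns are flagged and left at zero) and
zero-pads each trial by the extreme lags (100 ms before onset, 300 ms after
offset at the defaults).

The auditory filterbank width is three channel spacings (Q about 5). At
sharper tuning the low glottal harmonics of the synthetic words are
resolved individually and inject spectral-modulation energy at 2–4
cycles/octave, masking the low-pass modulation profile that broadband
speech-like signals show; Q about 5 matches typical cochlear-model tuning
and restores it.

## Encoding and decoding models

The encoding model regresses each sensor's series on the stimulus features
concatenated over lags (default fit range −100 to 300 ms; prediction uses
the interior 0–250 ms to avoid edge artefacts). `fit_ridge()` solves the
penalized normal equations in closed form with an unpenalized intercept;
`fit_banded()` applies one penalty per feature-space block (17 x 17 = 289
pairs for two bands). The lambda grid is 17 log2-equispaced values from 2^0
to 2^20; the printed grids in this literature are not always arithmetically
consistent, so the grid is configurable while preserving count, range, and
log spacing.

`trf_loto()` implements leave-one-trial-out cross-validation in the
weight-averaging form: one model is fitted per training trial and the
averaged weights predict the held-out trial; accuracy is the Pearson
correlation per output unit. `select_lambda()` takes, per (participant,
condition) cell, the grid argmax of the trial- and unit-averaged accuracy,
and returns the modal argmax across cells, breaking all ties toward the
smaller penalty so the choice is deterministic; an alternative reading —
the lambda maximizing the pooled accuracy — can be obtained by averaging
the accuracy table before selection, but the argmax-mode is the default.

For decoding, `decode_setup()` projects the sensors onto principal
components fitted on all trials jointly (50 retained by default, fewer with
a warning when rank is lower) and `decode()` maps the lagged components
back to the 25 modulation series. `single_lag_decode()` fits one model per
lag from −50 to 250 ms, optimizing lambda per lag, to resolve *when*
stimulus information is present in the response.

A practical note on the weight-averaging estimator: when single trials are
shorter than the number of lagged predictors, each per-trial fit is
underdetermined and the averaged weights are a biased (shrunken) estimate.
Correlation-based accuracy is insensitive to isotropic shrinkage but not to
the anisotropic shrinkage induced by temporally smooth predictors, which
caps noiseless decoding accuracy below 1 even with unlimited trials. The
package's consistency checks therefore use trial lengths that make the
per-trial problems full rank, and the decoding-consistency simulation uses
an impulse response kernel (`make_ground_truth(kernel_type = "impulse")`),
for which the stimulus-to-sensor map is exactly linearly invertible.

## Inference on model accuracies

`select_top_sensors()` keeps the 20 best sensors per hemisphere (per
participant and feature space). `rm_anova_2x3()` is a hand-rolled two-way
within-subject ANOVA (2 prior x 3 detail): main effects, interaction, and
simple effects of detail at each prior level, with partial eta squared and
Greenhouse–Geisser-corrected p-values for effects involving the 3-level
factor; it is cross-checked against `aov()` error strata in the tests.
Sphericity correction is applied because 3-level within factors routinely
violate it and the (2, 40)-df design cannot verify it from two samples.

Two permutation null schemes are provided. `shuffle_within_trial()` applies
one joint permutation over all (cell, time) entries of a trial's feature
matrix; `shuffle_across_trials()` permutes the word-to-trial assignment
while keeping each word's features intact, within each condition cell (the
nulls are per condition), excluding the identity permutation whenever an
alternative exists. `null_distribution()` re-runs the full cross-validated
accuracy pipeline per permutation at the lambda fixed from the unshuffled
fit, and `zscore_vs_null()` standardizes observed accuracies against the
per-condition null mean and SD. `fdr_bh()` applies Benjamini–Hochberg
step-up control, used across the 25 modulation cells (or across lags, for
the single-lag curves) as a flat family. `interaction_contrast()` computes
the diagnostic contrast (12 − 3 channels under Mismatch) − (12 − 3 channels
under Match) per unit with a one-sample t across participants and FDR
across units.

## The synthetic-data generator

The generator defines the study conditions for every test in the package:

* **Design**: `make_design()` builds the 3 (detail: 3/6/12 channels) x 2
  (prior: Match/Mismatch) factorial with equal cells (78 per cell and 3
  blocks of 156 at the study scale), every word spoken exactly once, and
  written words on Mismatch trials drawn as a fixed-point-free permutation
  of the Mismatch spoken words. The pairing rule beyond "permute the word
  list" is underdetermined; we use a uniform random derangement.
* **Audio**: `synth_word_audio()` produces parametric monosyllables —
  a harmonic source (f0 about 105–135 Hz with declination) shaped by three
  time-varying formant resonances via short-time spectral multiplication,
  consonant onsets/codas as noise bursts, fricative noise or nasal murmur,
  and a syllable envelope; durations are drawn from 372–903 ms (mean 591,
  SD 78). These exercise the vocoder and the modulation filterbank with
  controllable content but do not reproduce natural speech statistics:
  connected-speech co-articulation, speaker variability, and the exact
  modulation spectrum of real words are out of scope, so passing acoustic
  tests demonstrates correct machinery, not claims about natural speech.
  `synth_ripple_word()` generates word-length stimuli whose spectral detail
  is concentrated at 1.4 cycles/octave and 3 Hz — detail a 24-channel
  vocoder transmits but a 1-channel vocoder destroys — used to probe the
  vocoding contrast under controlled conditions.
* **Neural data**: `make_ground_truth()` draws a TRF whose lag kernel has a
  dominant peak at 87.5 ms and a weaker opposite-polarity peak at 150 ms
  (width 18 ms), multiplied by random feature-by-sensor loadings;
  `synth_neural()` convolves prepared features with it, scales by a
  per-condition gain, and adds white Gaussian sensor noise. Sensors carry a
  synthetic planar layout coordinate whose sign assigns the hemisphere.
  Gaussian white noise is the simplest model satisfying the linear-model
  assumptions; spatially correlated noise is deliberately deferred.
* **The interaction**: condition-dependent encoding gain (Mismatch
  0.5/1/1.5 and Match 1.5/1/0.5 across 3/6/12 channels,
  `crossover_gains()`) is the generator's mechanism for the
  detail-by-prior interaction. It is a stand-in producing the right
  accuracy pattern, not a mechanistic model of prediction error.
  `simulate_crossover_experiment()` runs the full chain for a cohort of
  simulated participants (8 by default, 4 trials per cell, 4 features, 10
  sensors, noise SD 1 — sizes chosen so one experiment takes about a
  second while the interaction is detected with high power) and returns the
  accuracy tables and ANOVA.

## The schematic coding-scheme simulation

`run_schematic_grid()` reproduces the two schemes at the level of pixel
patterns: written words rasterized as binary glyph matrices (the built-in
"clay"/"fast" pair, rendered at 3 pixels per glyph cell so that local-mean
degradation blurs within letter strokes), degraded by averaging over eight
("low") or four ("medium") local pixels or left intact ("high"), plus
uniform noise of SD 0.5 and normalization to unit sum (resampling the rare
non-positive sums). The sharpened representation is the normalized product
of input and prediction; the prediction-error representation is their
unnormalized difference; fidelity is the squared Pearson correlation with a
clean rendering of the heard word, and the total prediction-error magnitude
is the sum of absolute PE over pixels. The kernels are 2x2 (four pixels)
and 3x3-minus-centre (eight pixels), with periodic boundary handling so
mean filtering preserves the total sum exactly. At coarser rendering the
two words' patterns correlate strongly and the Mismatch fidelity curve
loses monotonicity; the finer rendering restores the published behaviour of
both schemes.

## DSS denoising of TRFs

`dss_fit()` ranks spatial components by trial-to-trial consistency: the
covariance of the trial average is diagonalized against the summed
single-trial covariance (summing over lags/features and conditions,
unnormalized) after whitening with a relative eigenvalue threshold of
1e-10 for rank control. `dss_denoise()` keeps the first components
(3 by default) and back-projects; `sensor_rms()` summarizes the denoised,
trial-averaged TRF as an RMS time course over a sensor subset (e.g. the
left hemisphere), whose peaks recover the generating kernel latencies in
simulation.

## Pipeline, formats and reproducibility

`run_pipeline()` chains simulate → vocode → features → fit → select →
ANOVA → permute → acoustics → schematic → DSS at a configurable scale
(`pipeline_config()` validates keys and rejects unknown ones) and writes
CSV/JSON results plus a provenance manifest (config hash, seed, package
version). Every random stage derives its seed from the single config seed,
so a rerun is byte-identical. Audio is written as 16-bit PCM WAV; epoched
data live in a plain-text directory bundle (JSON attributes, CSV datasets
for the trial x sensor x sample array, sensor table, and per-trial feature
stores) with round-trip error below 1e-9. The demo scale (4 trials/cell,
6 participants, 16 sensors, a 6-channel spectrogram feature space) runs in
well under a minute; study-scale runs are a matter of scaling the config.

## Problem sizes used by the validation suite

The packaged checks run at deliberately small scales: ridge-oracle
agreement on 100 random instances up to 20 x 8; latency recovery on 12
words per cell, 20 sensors, SNR 0 dB; decoding consistency on 12 trials of
150-sample band-limited streams with rank-matched components; interaction
detection over 100 simulated 8-participant experiments; null calibration
over 100 true-null datasets with 40 permutations each; 1000 schematic
repetitions; and acoustic grids over 8 natural-like plus 10 ripple words.
These sizes were chosen as the smallest at which each property is sharply
decided.

## Known limitations

* Parametric words are not recordings; acoustic conclusions transfer to
  real speech only qualitatively. In particular the decrease of 0.5
  cycles/octave modulation energy with more vocoder channels reported for
  natural word sets does not emerge for these stimuli (their strong static
  spectral tilt survives 24-channel vocoding and dominates that cell), so
  the vocoding contrast is validated on the ripple set where the effect
  direction is unambiguous.
* The weight-averaging cross-validation estimator is biased for
  underdetermined single-trial fits (see above); absolute accuracies from
  short trials should be compared within, not across, trial-length regimes.
* Noise is white across sensors and time; evoked-noise correlations,
  subject variability beyond gain and noise level, and realistic MEG
  forward models are not modelled.
* Behavioral clarity ratings and anything requiring the original subject
  recordings are out of scope.
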