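---
title: "Auditory evoked responses from simultaneous EEG and fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditory evoked responses from simultaneous EEG and fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abrnirs)
```

# Scope

`abrnirs` implements two complementary analyses of auditory evoked
responses recorded in parallel with EEG and functional near-infrared
spectroscopy (fNIRS), together with a seeded synthetic-data generator that
produces recordings with known ground truth:

1. **Click paradigm (ABR pipeline).** Millisecond-scale auditory brainstem
   responses (Jewett waves I, III, V) evoked by broadband click trains,
   extracted from EEG by band-pass filtering, epoching and averaging, and
   scored by windowed peak detection. The fNIRS total-hemoglobin trace is
   mirrored onto the same epoch timeline and compared by time-locked
   cross-correlation.
2. **Warble paradigm (block-design battery).** Second-scale cortical
   hemodynamic responses to a 2-s "warble" stimulus embedded in a fixed
   92-s block design, analysed by a battery of conceptually distinct
   tests: grand averaging, PCA of epoched responses, a task GLM with FDR
   correction, time-locked cross-correlation, stimulation-versus-silence
   contrasts and a spatial repeated-measures ANOVA with Holm-corrected
   post-hoc pairs.

# Stimulation protocols and calibration

Stimulus levels are converted to headphone drive voltages through the
voltage-ratio relation for sound pressure,
$dB_1 - dB_2 = 20\log_{10}(V_1/V_2)$, anchored at a single calibration
point (by convention 370 mV at 100 dB SPL). The inversion
$V_2 = V_1\,10^{(dB_2-dB_1)/20}$ is exact, strictly increasing and
round-trips with `voltage_to_db()` to machine precision.

The click protocol is three contiguous blocks of 1000 rectangular 0.1-ms
clicks at a repetition rate of 81.9 Hz, one block per level (50, 70,
90 dB SPL), giving an inter-onset interval of 12.21 ms. Blocks are
concatenated without a gap by default (`inter_block_gap` makes this
configurable). The warble protocol is the fixed 92-s sequence 30 s
silence / 2 s @ 50 dB / 13 s / 2 s @ 70 dB / 13 s / 2 s @ 90 dB / 30 s
silence, so warble onsets fall at 30, 45 and 60 s. The warble waveform
itself (`synth_warble_samples()`) is a zero-mean alternating-polarity
pulse train; the internal pulse rate is not fixed by the protocol and
defaults to 100 pulses/s.

# The synthetic-data generator

No public recordings accompany the paradigms, so every pipeline stage is
validated against simulated data with recoverable ground truth. The
generators are pure functions of their parameters and a seed.

## EEG / ABR

Each click adds a fixed template to the EEG: the sum of three Gaussian
bumps (0.4 ms full width at half maximum) at the wave I/III/V latencies
and amplitudes for that click's level; responses of successive clicks
superpose linearly and white Gaussian noise is added per channel. Default
latencies shorten and amplitudes grow with level (e.g. wave V: 7.4 ms /
0.45 uV at 50 dB to 6.0 ms / 1.0 uV at 90 dB), all inside the clinical
scoring windows (I: 1.6-3.5, III: 3.6-5.5, V: 5.6-8.0 ms). The default
noise SD of 10 uV puts the single-trial wave-V SNR near 0.1 at 90 dB,
typical of raw ABR sweeps, so that only averaging hundreds of epochs
reveals the response.

The simulation sample rate defaults to 16 kHz: a 100-3000 Hz analysis
band and 0.1-ms features require at least a 6 kHz rate by Nyquist, and
16 kHz leaves comfortable headroom for latency quantization (1/16 ms per
sample). A silent pre-roll (default 1 s) precedes the first click so the
continuous pre-block baseline exists for the first intensity block.

## fNIRS

Raw intensity per channel is
$\text{baseline}\,(1 + \beta_{ch}\, r(t) + s(t) + d(t)) + \varepsilon$,
where $r(t)$ is a gamma-density kernel normalized to peak 1 with its mode
`trough_latency` seconds (default 12 s, the midpoint of the expected
10-15 s range) after each warble onset. A negative $\beta_{ch}$ therefore
produces the characteristic slow task-locked intensity decrease. Default
channel amplitudes are heterogeneous across the eight channels
(-0.6% to -2.3%), with a null channel allowed. The systemic term $s(t)$
sums three sinusoids shared by all channels - cardiac (~1.1 Hz, 0.5% of
baseline), respiratory (~0.3 Hz, 0.3%) and vasomotor (~0.1 Hz, 0.3%) -
with seeded random phases; $d(t)$ is a linear drift (1e-4/s) and
$\varepsilon$ white noise (0.5% of baseline). These magnitudes are typical
of continuous-wave optical recordings, where the cardiac pulsation is the
dominant visible oscillation.

The paired chromophore recording carries, per channel, a Delta-HbO rise
and a Delta-HbR dip of one quarter the magnitude, so total hemoglobin
Delta-HbT = Delta-HbO + Delta-HbR increases with the response; the
identity holds exactly by construction at every stage that carries all
three traces. Raw intensity is a single trace per channel: wavelength-
resolved optics and the Beer-Lambert reconstruction are out of scope, as
the analyses consume either raw intensity or ready-made chromophores.

The breath-hold generator adds a slow excursion that is *identical on
every channel* - a deliberately global systemic event used to verify that
the spatial ANOVA classifies uniform artifacts as non-specific.

## What the generator does not emulate

Motion artifacts, optode-coupling changes, heteroscedastic noise,
short-channel scalp hemodynamics and non-stationary systemic rhythms are
absent. Passing tests therefore demonstrate correctness of the analysis
chain under the stated signal model, not robustness to every artifact
class of real recordings.

# ABR pipeline choices

* **Filtering** is a 4th-order Butterworth band-pass (100-3000 Hz)
  applied forward-backward (`signal::filtfilt`), because zero-phase
  filtering is required for unbiased latency scoring; only the cutoffs
  are fixed by the protocol.
* **Epochs** run 0 to +12 ms after each click, with no pre-stimulus
  samples: at 81.9 Hz the inter-stimulus interval is 12.21 ms, so epochs
  never overlap but also cannot contain a 0.5-s baseline. Baseline
  statistics are instead computed from the 0.5 s of continuous filtered
  signal immediately preceding each intensity block. Note that for the
  second and third blocks this segment contains the ongoing response to
  the previous block - a property of continuous stimulation itself, not
  of the implementation.
* **Averaging** subtracts the pre-block baseline mean, then normalizes to
  the peak absolute amplitude; the pre-normalization scale is retained so
  SNR can be computed in physical units. An all-zero average skips
  normalization and flags itself.
* **SNR** is (peak - baseline mean) divided by the baseline SD *on the
  averaged-waveform scale*, i.e. the continuous-baseline SD scaled by
  $1/\sqrt{n}$, because the peak is read from an n-trial average while the
  stored baseline SD is single-trial noise.
* **Peak scoring**: local maxima at least 0.08 (normalized) high, with a
  global 2-ms minimum separation enforced greedily in order of
  decreasing amplitude (ties: earliest), are assigned to the wave
  windows; the highest qualifying peak per window wins and unassigned
  peaks are reported as extra peaks. Absence of a wave is a result, not
  an error. The implementation is tested against a brute-force
  enumeration oracle.
* **Cross-modal comparison** resamples both waveforms onto a 256 Hz grid
  (lag quantum 3.90625 ms) and reports the signed correlation at the lag
  of maximum absolute correlation within +/-10 ms. On a 12-ms epoch this
  grid holds only four points, so lags of +/-2 steps leave too little
  overlap and are skipped; the statistic is correspondingly coarse, which
  is an honest reflection of fNIRS temporal resolution rather than a
  limitation of the estimator.

# Warble battery choices

* **Smoothing** is a centered 200-ms moving average with edge
  truncation - enough to suppress sample noise while preserving the
  seconds-scale response.
* **Percent-change epochs** span -5 to +15 s around each onset,
  referenced to the mean raw intensity over -5 to 0 s.
* **The GLM design** has an intercept, a linear drift and one task
  regressor: 2-s boxcars at the warble onsets convolved with a
  negative-going gamma kernel peaking 12 s after onset. With this sign
  convention an intensity *decrease* yields a *positive* amplitude
  estimate, while the cross-correlation against the positive-going
  version of the same regressor yields *negative* peaks - matching the
  customary presentation of both statistics.
* **Per-channel significance** comes from a circular-shift permutation
  test (199 deterministic, evenly spaced shifts of the task regressor, all
  at least 5 s from true alignment). The parametric OLS t-test is
  reported but is not calibrated under narrowband systemic noise: the
  sinusoidal components inflate the residual variance estimate far more
  than they perturb the amplitude estimate, deflating the null t
  distribution (measured SD ~0.8 instead of 1). Shifting the regressor
  preserves the full autocorrelation structure of the noise and restores
  the nominal false-positive rate, as the null-cohort tests verify.
* **Group inference** is the summary-statistics approach: per-subject
  OLS amplitudes, then a one-sample t-test across subjects per channel,
  Benjamini-Hochberg correction across channels, significance at
  corrected p < 0.05. A full mixed model is out of scope.
* **Stimulation-vs-silence contrasts** pair each 2-s stimulation segment
  with each equal-length silence segment; silence segments are the 2-s
  windows immediately preceding each onset (the protocol does not define
  their placement, and the immediately preceding window length-matches
  while staying clear of the previous response trough). Each pair yields
  a Pearson correlation of the two time courses and a two-sample t-test;
  matrices are averaged across channels and subjects, marks are placed at
  |r| > 0.25 and p < 0.05, and all channel-level p-values feed a
  histogram with 0.005-wide bins so one bin edge falls exactly at 0.05.
* **Spatial ANOVA** is the one-way repeated-measures F with channel as
  the within-subject factor, df (C-1, (C-1)(S-1)), computed via
  `stats::aov` with a subject error stratum; no sphericity correction is
  applied by default, and the degenerate all-channels-identical case
  (0/0) is defined as F = 0, p = 1. Post-hoc all-pairs paired t-tests are
  Holm-corrected. Holm and Benjamini-Hochberg corrections delegate to
  `stats::p.adjust` and are tested against textbook step-down/step-up
  enumerations.

# Numerical and interface conventions

Event timestamps are seconds from recording start, 0-based, with
half-open durations, everywhere. Channel indices are 1-based in
human-facing tables ("Ch 1") and 0-based only where a format requires it.
EEG recordings serialize to EDF+C (16-bit integers with per-channel
scaling, events as annotation lists), so EDF round-trips are exact only
to the format's quantization step - about 1/65000 of each channel's
range; fNIRS recordings serialize to SNIRF (HDF5, float64) and round-trip
to machine precision. Result tables are written as CSV plus a JSON
bundle.

# Problem sizes used in the checks

The test-suite and acceptance computations run the full study designs
where the quantity checked depends on them (34-subject warble cohorts,
20-subject ABR cohorts, 1000-trial averages, 100-seed recovery runs,
500-test error-rate estimates) and reduced click counts (30 per
intensity) where the quantity is a bookkeeping identity that is invariant
to trial count, such as the 2,280-waveform inventory of a 20-subject
run. Each reported rate states its denominator.

# Known limitations

* The ABR scorer operates on normalized waveforms; absolute amplitude
  comparisons across conditions must use the retained normalization
  factor.
* The epoch-space reference for PCA shape recovery is the injected
  kernel; epoch averages themselves are slightly contaminated by the
  tails of preceding responses (inter-onset spacing 15 s versus a kernel
  that has not fully returned to baseline), which is visible as a
  depressed pre-stimulus baseline in later epochs.
* Single-subject GLM p-values assume stationary noise within a
  recording; slow non-stationarities beyond a linear drift are not
  modeled.
* The cross-modal correlation on 12-ms epochs is computed from very few
  grid points and should be interpreted as a coarse alignment check, not
  an effect-size estimate.
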