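# abrnirs

Analysis of auditory evoked responses recorded simultaneously with EEG and
functional near-infrared spectroscopy (fNIRS), for auditory neurophysiology
and audiological research.

Two paradigms are covered end to end:

* **Click ABR (EEG + fNIRS).** Broadband click trains at 81.9 Hz evoke
  millisecond-scale auditory brainstem responses (Jewett waves I, III, V).
  The pipeline band-passes the EEG (100–3000 Hz, zero-phase Butterworth),
  cuts 12-ms epochs per click, averages per channel × intensity, normalizes
  to peak, scores waves in clinical latency windows (I: 1.6–3.5 ms,
  III: 3.6–5.5 ms, V: 5.6–8.0 ms; minimum height 0.08, minimum separation
  2 ms), and reports latencies, amplitudes, inter-peak intervals, latency
  deviations from normative values and SNR. The fNIRS total-hemoglobin
  trace ΔHbT = ΔHbO + ΔHbR is mirrored onto the same epoch timeline and
  compared by time-locked cross-correlation (±10 ms window, 3.90625 ms lag
  steps).
* **Warble block design (fNIRS).** A 2-s "warble" stimulus at 50/70/90 dB
  SPL inside a fixed 92-s block sequence elicits a slow cortical
  hemodynamic response: a raw-intensity decrease troughing 10–15 s after
  onset. A battery of tests characterizes it: grand average with SEM, PCA
  of percent-change epochs, a task GLM
  (y = β·[boxcar ⊗ hemodynamic kernel] + drift + ε) with per-channel
  circular-shift permutation p-values, group one-sample t with
  Benjamini–Hochberg FDR, time-locked cross-correlation, stimulation-vs-
  silence correlation/t-test matrices, and a spatial repeated-measures
  ANOVA (channel as within-subject factor, df = (C−1, (C−1)(S−1))) with
  Holm-corrected post-hoc pairs — distinguishing localized neural
  responses from global systemic artifacts.

Because no public recordings exist for these paradigms, the package ships a
seeded synthetic-data generator (`simulate_abr()`, `simulate_fnirs()`,
`simulate_breath_hold()`, `make_null_cohort()`) producing EEG and fNIRS
recordings with known ground truth, so every stage is verifiable.
Recordings read and write standard formats: EDF+C for EEG and SNIRF (HDF5)
for fNIRS, plus TSV event tables and CSV/JSON reports.

## Worked example

Score a simulated 1000-sweep ABR average at 90 dB SPL:

```r
library(abrnirs)
protocol <- build_click_protocol()              # 3 x 1000 clicks @ 81.9 Hz
rec <- bandpass(simulate_abr(protocol, abr_truth(seed = 7)))
wf  <- average_and_normalize(epoch_clicks(rec))[[3]]   # channel 1 @ 90 dB
detect_waves(wf)
#> <wave_score> EEG01 @ 90 dB
#>  wave present latency_ms amplitude
#>     I    TRUE     2.0000 0.5554451
#>   III   FALSE         NA        NA
#>     V    TRUE     5.9375 1.0000000
```

Wave V — the clinically decisive peak — is recovered at 5.94 ms (injected:
6.0 ms); wave III is lost in this subject's noise, which the scorer reports
as absence rather than forcing a peak. `snr(wf)` gives 4.29: the peak of
the 1000-trial average is ~4 baseline standard deviations (on the averaged
scale) above the pre-stimulus baseline.

Run the full warble battery on a simulated 12-subject cohort:

```r
b <- run_study2(study2_config(n_subjects = 12, seed = 42))
b$glm_table
#>   channel t_statistic  p_value mean_beta    p_fdr significant
#> 1    Ch 1        19.1 8.81e-10   0.01317 2.12e-09        TRUE
#> 2    Ch 2        19.3 7.75e-10   0.02296 2.12e-09        TRUE
#> 3    Ch 3        17.9 1.78e-09   0.03756 2.49e-09        TRUE
#> ...
b$anova
#> <spatial_anova> F(7, 77) = 292.7381, p = 9.302e-53
```

Every channel carries a significant response after FDR correction; the
`mean_beta` column is the fractional intensity decrease recovered per
channel (the generator injected 0.6–2.3%). PC1 of the pooled epochs
explains 44.9% of the variance and matches the injected hemodynamic
kernel; the spatial ANOVA rejects uniformity across channels, the
signature of a localized (non-systemic) response — on breath-hold
simulations, where the excursion is identical on every channel, it rejects
at chance only.

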