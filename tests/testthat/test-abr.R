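test_that("band-pass filter passes the band and rejects out-of-band tones", {
  fs <- 16000
  t <- seq(0, 1, by = 1 / fs)
  in_band <- sin(2 * pi * 500 * t)
  low_tone <- sin(2 * pi * 10 * t)
  rec <- time_series_recording(rbind(in_band, low_tone, 0 * t), fs,
                               c("a", "b", "c"), modality = "eeg")
  out <- bandpass(rec)
  mid <- seq(round(0.2 * fs), round(0.8 * fs))  # avoid filter edge effects
  gain_pass <- max(abs(out$data[1, mid])) / max(abs(in_band[mid]))
  expect_gt(gain_pass, 0.95)
  expect_lt(gain_pass, 1.05)
  gain_stop <- max(abs(out$data[2, mid])) / max(abs(low_tone[mid]))
  expect_lt(gain_stop, 0.1)  # >= 20 dB attenuation
  expect_equal(out$data[3, ], rep(0, length(t)), ignore_attr = TRUE)
  expect_error(bandpass(time_series_recording(matrix(0, 1, 100), 500, "a",
                                              modality = "eeg")),
               "sample_rate")
})

test_that("click epoching groups by channel and intensity with full bookkeeping", {
  pr <- build_click_protocol(clicks_per_intensity = 20)
  tr <- abr_truth(noise_sd = 0)
  rec <- simulate_abr(pr, tr, n_channels = 4)
  es <- epoch_clicks(rec)
  expect_equal(length(es$groups), 4 * 3)
  counts <- vapply(es$groups, function(g) g$n_epochs, 0L)
  expect_true(all(counts == 20))
  # conservation: sum of group sizes = accepted events x channels
  n_clicks <- sum(rec$events$kind != "silence")
  expect_equal(sum(counts) + es$n_dropped, n_clicks * 4)
  ints <- vapply(es$groups, function(g) g$intensity, 0)
  expect_equal(sort(unique(ints)), c(50, 70, 90))
})

test_that("epochs that escape the recording are dropped and counted", {
  pr <- build_click_protocol(clicks_per_intensity = 10, intensities = 90)
  tr <- abr_truth(intensities = 90, latencies_ms = cbind(`90` = c(2, 4, 6)),
                  amplitudes = cbind(`90` = c(.2, .4, 1)), noise_sd = 0)
  rec <- simulate_abr(pr, tr, post_s = 0)
  # truncate so the last epoch cannot fit
  rec$data <- rec$data[, seq_len(ncol(rec$data) - 150), drop = FALSE]
  es <- epoch_clicks(rec)
  expect_equal(es$groups[[1]]$n_epochs + es$groups[[1]]$n_dropped, 10)
  expect_gt(es$n_dropped, 0)
  # no events at all
  rec$events <- rec$events[0, ]
  expect_length(epoch_clicks(rec)$groups, 0)
})

test_that("averaging subtracts the pre-block baseline and normalizes to peak", {
  pr <- build_click_protocol(clicks_per_intensity = 1000, intensities = 90)
  # white-noise epochs: residual after averaging follows the 1/sqrt(n) law
  trn <- abr_truth(intensities = 90, latencies_ms = cbind(`90` = c(2, 4, 6)),
                   amplitudes = cbind(`90` = c(0, 0, 0)), noise_sd = 1,
                   seed = 8)
  rec <- simulate_abr(pr, trn)
  wf <- average_and_normalize(epoch_clicks(rec))[[1]]
  resid_sd <- stats::sd(wf$values * wf$norm_factor)
  expect_equal(resid_sd, 1 / sqrt(1000), tolerance = 0.1)
  expect_equal(max(abs(wf$values)), 1)
  expect_equal(wf$n_averaged, 1000)
})

test_that("constant recordings average to zero and skip normalization", {
  pr <- build_click_protocol(clicks_per_intensity = 5, intensities = 90)
  tr <- abr_truth(intensities = 90, latencies_ms = cbind(`90` = c(2, 4, 6)),
                  amplitudes = cbind(`90` = c(0, 0, 0)), noise_sd = 0)
  rec <- simulate_abr(pr, tr)
  rec$data <- rec$data + 3.7  # constant offset everywhere
  wf <- average_and_normalize(epoch_clicks(rec))[[1]]
  expect_false(wf$normalized)
  expect_lt(max(abs(wf$values)), 1e-9)  # offset removed via baseline
})

test_that("wave scoring assigns window peaks and computes inter-peak intervals", {
  fs <- 16000
  t_ms <- (0:(round(0.012 * fs)) ) / fs * 1000
  v <- bump(t_ms, 2.5, 0.3) + bump(t_ms, 4.5, 0.6) + bump(t_ms, 6.5, 1.0)
  sc <- detect_waves(make_wf(v / max(abs(v))))
  expect_true(all(sc$waves$present))
  expect_equal(sc$waves$latency_ms, c(2.5, 4.5, 6.5), tolerance = 1e-2)
  expect_equal(unname(sc$intervals["I_V"]), 4.0, tolerance = 2e-2)
  expect_equal(unname(sc$intervals["I_III"]), 2.0, tolerance = 2e-2)
  # flat waveform: absence is a valid result
  sc0 <- detect_waves(make_wf(rep(0, 192)))
  expect_false(any(sc0$waves$present))
  expect_true(all(is.na(sc0$intervals)))
  # sub-threshold bump is not scored
  v2 <- bump(t_ms, 7.0, 0.05)
  sc2 <- detect_waves(make_wf(v2))
  expect_false(sc2$waves$present[3])
})

test_that("peaks outside the scoring windows are reported as extra peaks", {
  fs <- 16000
  t_ms <- (0:(round(0.012 * fs))) / fs * 1000
  v <- bump(t_ms, 6.5, 1.0) + bump(t_ms, 10.5, 0.5)
  sc <- detect_waves(make_wf(v))
  expect_true(sc$waves$present[3])
  expect_equal(nrow(sc$extra_peaks), 1)
  expect_equal(sc$extra_peaks$latency_ms, 10.5, tolerance = 1e-2)
})

test_that("peak detection equals the brute-force oracle on random waveforms", {
  fs <- 16000
  dist_samples <- 2 / 1000 * fs
  for (seed in 1:40) {
    v <- random_waveform(n = 192, seed = seed)
    got <- abrnirs:::find_peaks(v, 0.08, dist_samples)
    want <- oracle_find_peaks(v, 0.08, dist_samples)
    expect_identical(got, want)
  }
})

test_that("latency deviation is the signed difference from normative values", {
  fs <- 16000
  t_ms <- (0:(round(0.012 * fs))) / fs * 1000
  sc <- detect_waves(make_wf(bump(t_ms, 6.8, 1.0)))
  dev <- latency_deviation(sc, c(I = 1.6, III = 3.8, V = 5.6))
  # one sample-grid step (1/16 ms) of quantization is allowed
  expect_lt(abs(dev$deviation_ms[dev$wave == "V"] - (6.8 - 5.6)), 0.05)
  expect_true(is.na(dev$deviation_ms[dev$wave == "I"]))  # absent wave
  sc2 <- detect_waves(make_wf(bump(t_ms, 5.6, 1.0)))
  dev2 <- latency_deviation(sc2, c(V = 5.6))
  expect_lt(abs(dev2$deviation_ms[dev2$wave == "V"]), 0.05)
})

test_that("SNR is peak over baseline SD and grows with injected amplitude", {
  # peak 5 relative to baseline mean 1 with baseline sd 2 -> (5-1)/2 = 2
  wf <- make_wf(c(0.1, 1, 0.2) / 1, norm_factor = 4, baseline_mean = 1,
                baseline_sd = 2)
  expect_equal(snr(wf), 2)
  expect_equal(snr(make_wf(rep(0, 10), baseline_sd = 2)), 0)
  expect_error(snr(make_wf(rep(1, 10), baseline_sd = 0)), "SNR undefined")
  # monotone in amplitude at fixed noise
  pr <- build_click_protocol(clicks_per_intensity = 60, intensities = 90)
  amps <- seq(0.5, 6, length.out = 12)
  snrs <- vapply(seq_along(amps), function(i) {
    tr <- abr_truth(intensities = 90,
                    latencies_ms = cbind(`90` = c(2, 4, 6)),
                    amplitudes = cbind(`90` = c(0.2, 0.4, 1) * amps[i]),
                    noise_sd = 5, seed = 100 + i)
    rec <- bandpass(simulate_abr(pr, tr))
    snr(average_and_normalize(epoch_clicks(rec))[[1]])
  }, 0)
  expect_gt(stats::cor(amps, snrs, method = "spearman"), 0.9)
})

test_that("fNIRS click trace passes HbT through and baseline-corrects", {
  fs <- 10
  n <- 400
  tt <- (seq_len(n) - 1) / fs
  # HbO = 2t, HbR = -t  =>  HbT = t
  data <- rbind(2 * tt, -tt)
  ev <- data.frame(onset = 20, duration = 1e-4, intensity = 90,
                   kind = "click")
  rec <- time_series_recording(data, fs, c("S1-D1 HbO", "S1-D1 HbR"),
                               events = ev, modality = "fnirs_chromophore")
  wfs <- fnirs_click_trace(rec, target_rate = 1000)
  expect_length(wfs, 1)
  wf <- wfs[[1]]
  raw_vals <- wf$values * wf$norm_factor
  # linear ramp through the epoch: slope 1 per second on the HbT scale,
  # spanning (nsamp - 1)/rate = 11 ms
  expect_equal(diff(range(raw_vals)), 0.011, tolerance = 1e-6)
  # baseline mean of t over [18,20) is ~19 < value at epoch start (20)
  expect_equal(raw_vals[1], 20 - wf$baseline_mean, tolerance = 0.2)
  # constant signal: zero after baseline correction
  rec2 <- time_series_recording(rbind(rep(2, n), rep(-1, n)), fs,
                                c("S1-D1 HbO", "S1-D1 HbR"), events = ev,
                                modality = "fnirs_chromophore")
  wf2 <- fnirs_click_trace(rec2, target_rate = 1000)[[1]]
  expect_false(wf2$normalized)
  expect_lt(max(abs(wf2$values)), 1e-9)
  # missing HbR is an error
  rec3 <- time_series_recording(matrix(tt, 1), fs, "S1-D1 HbO",
                                events = ev,
                                modality = "fnirs_chromophore")
  expect_error(fnirs_click_trace(rec3), "HbR")
})

test_that("cross-modal correlation finds the right sign, magnitude and lag", {
  step_ms <- 1000 / 256
  t_ms <- (0:40) * step_ms
  a <- make_wf(sin(2 * pi * t_ms / 60), sample_rate = 256)
  expect_equal(crossmodal_correlation(a, a), list(r = 1, lag_ms = 0))
  neg <- make_wf(-a$values, sample_rate = 256)
  got <- crossmodal_correlation(a, neg)
  expect_equal(got$r, -1)
  expect_equal(got$lag_ms, 0)
  # second waveform delayed by one grid step -> lag +3.90625 ms
  shifted <- make_wf(c(a$values[1], a$values[-length(a$values)]),
                     sample_rate = 256)
  got2 <- crossmodal_correlation(a, shifted)
  expect_equal(got2$lag_ms, step_ms)
  expect_gt(abs(got2$r), 0.99)
})
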