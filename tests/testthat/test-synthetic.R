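one_click_protocol <- function(intensity = 90) {
  build_click_protocol(rate = 81.9, clicks_per_intensity = 1,
                       intensities = intensity)
}

truth_90 <- function(...) {
  abr_truth(intensities = 90,
            latencies_ms = cbind(`90` = c(2.0, 4.0, 6.0)),
            amplitudes = cbind(`90` = c(0.2, 0.4, 1.0)), ...)
}

test_that("noiseless ABR simulation puts wave maxima at the true latencies", {
  tr <- truth_90(noise_sd = 0)
  rec <- simulate_abr(one_click_protocol(), tr, pre_s = 0.01)
  fs <- rec$sample_rate
  onset <- rec$events$onset[1]
  t_ms <- ((seq_len(ncol(rec$data)) - 1) / fs - onset) * 1000
  for (w in 1:3) {
    lat <- tr$latencies_ms[w, 1]
    win <- which(t_ms > lat - 0.8 & t_ms < lat + 0.8)
    peak_t <- t_ms[win][which.max(rec$data[1, win])]
    expect_equal(peak_t, lat, tolerance = 1000 / fs / 2 + 1e-9)
  }
})

test_that("ABR simulation is deterministic and respects linear superposition", {
  pr <- build_click_protocol(clicks_per_intensity = 5, intensities = 90)
  tr <- truth_90(noise_sd = 2, seed = 11)
  r1 <- simulate_abr(pr, tr)
  r2 <- simulate_abr(pr, tr)
  expect_identical(r1$data, r2$data)
  # superposition: a 2-click train equals the sum of two shifted 1-click runs
  tr0 <- truth_90(noise_sd = 0)
  pr2 <- build_click_protocol(clicks_per_intensity = 2, intensities = 90)
  both <- simulate_abr(pr2, tr0, pre_s = 0.05)
  single <- function(onset) {
    ev <- pr2$events[1, ]
    ev$onset <- onset
    p <- structure(list(events = ev, total_duration = pr2$total_duration,
                        repetition_rate = pr2$repetition_rate),
                   class = "stimulus_protocol")
    simulate_abr(p, tr0, pre_s = 0.05)$data
  }
  summed <- single(pr2$events$onset[1]) + single(pr2$events$onset[2])
  expect_equal(both$data, summed, tolerance = 1e-12)
})

test_that("pure-noise ABR recording has the requested variance", {
  pr <- build_click_protocol(clicks_per_intensity = 100, intensities = 90)
  tr <- abr_truth(intensities = 90,
                  latencies_ms = cbind(`90` = c(2, 4, 6)),
                  amplitudes = cbind(`90` = c(0, 0, 0)),
                  noise_sd = 1, seed = 5)
  rec <- simulate_abr(pr, tr, pre_s = 5)
  expect_gt(ncol(rec$data), 1e5)
  expect_equal(stats::var(rec$data[1, ]), 1, tolerance = 0.05)
})

test_that("ABR simulation validates its inputs", {
  tr <- truth_90()
  expect_error(simulate_abr(one_click_protocol(70), tr), "absent from truth")
  expect_error(simulate_abr(one_click_protocol(), tr, sample_rate = 500),
               "10 kHz")
  expect_error(abr_truth(latencies_ms = cbind(`50` = c(1.0, 4.8, 7.4),
                                              `70` = c(2.4, 4.4, 6.6),
                                              `90` = c(2.0, 4.0, 6.0))),
               "scoring window")
})

quiet_truth <- function(betas = c(-0.02, 0), ...) {
  hemo_truth(channel_betas = betas, cardiac_amp = 0, respiratory_amp = 0,
             vasomotor_amp = 0, drift_slope = 0, noise_sd = 0,
             chromo_noise_sd = 0, ...)
}

test_that("fNIRS simulation is flat with no effect, noise or systemic terms", {
  pr <- build_warble_protocol()
  sim <- simulate_fnirs(pr, quiet_truth(c(0, 0)),
                        channel_labels = c("S1-D1", "S1-D2"))
  expect_equal(max(abs(sim$raw$data - 1)), 0)
  expect_equal(max(abs(sim$chromophore$data)), 0)
})

test_that("fNIRS response troughs at onset + trough_latency", {
  pr <- build_warble_protocol()
  # single warble event so kernel tails cannot interact
  pr$events <- pr$events[pr$events$kind == "silence" | pr$events$onset == 30, ]
  sim <- simulate_fnirs(pr, quiet_truth(c(-0.02, 0)),
                        channel_labels = c("S1-D1", "S1-D2"))
  fs <- sim$raw$sample_rate
  i_min <- which.min(sim$raw$data[1, ])
  expect_equal((i_min - 1) / fs, 30 + 12, tolerance = 1 / fs + 1e-9)
  # trough depth equals the beta fraction
  expect_equal(min(sim$raw$data[1, ]), 1 - 0.02, tolerance = 1e-9)
  # null channel stays flat
  expect_equal(max(abs(sim$raw$data[2, ] - 1)), 0)
})

test_that("systemic oscillations are shared across channels", {
  pr <- build_warble_protocol()
  tr <- hemo_truth(channel_betas = rep(0, 3), drift_slope = 0, noise_sd = 0,
                   chromo_noise_sd = 0)
  sim <- simulate_fnirs(pr, tr, channel_labels = c("S1-D1", "S1-D2", "S2-D1"))
  expect_equal(stats::cor(sim$raw$data[1, ], sim$raw$data[2, ]), 1)
  expect_equal(stats::cor(sim$raw$data[1, ], sim$raw$data[3, ]), 1)
})

test_that("chromophore pairing satisfies HbT = HbO + HbR exactly", {
  pr <- build_warble_protocol()
  sim <- simulate_fnirs(pr, hemo_truth(seed = 42))
  hbo <- chromophore(sim$chromophore, "HbO")
  hbr <- chromophore(sim$chromophore, "HbR")
  hbt <- chromophore(sim$chromophore, "HbT")
  expect_lt(max(abs(hbt - (hbo + hbr))), 1e-12)
  # HbO rises, HbR dips, HbT increases around the response
  resp <- which.max(colMeans(hbo))
  expect_gt(mean(hbo[, resp]), 0)
  expect_lt(mean(hbr[, resp]), 0)
  expect_gt(mean(hbt[, resp]), 0)
})

test_that("fNIRS simulation validates inputs and is deterministic", {
  pr <- build_warble_protocol()
  expect_error(simulate_fnirs(pr, hemo_truth(), channel_labels = character(0)),
               "non-empty")
  expect_error(simulate_fnirs(pr, hemo_truth(channel_betas = c(-0.1, 0)),
                              channel_labels = "S1-D1"), "number of channels")
  s1 <- simulate_fnirs(pr, hemo_truth(seed = 9))
  s2 <- simulate_fnirs(pr, hemo_truth(seed = 9))
  expect_identical(s1$raw$data, s2$raw$data)
  expect_identical(s1$chromophore$data, s2$chromophore$data)
})

test_that("breath-hold excursions are global and vanish when disabled", {
  tr <- hemo_truth(channel_betas = rep(0, 4), seed = 3)
  labs <- c("S1-D1", "S1-D2", "S2-D1", "S2-D2")
  base <- simulate_fnirs(build_warble_protocol(), tr, channel_labels = labs)
  none <- simulate_breath_hold(tr, numeric(0), channel_labels = labs)
  expect_identical(none$raw$data, base$raw$data)
  zero_amp <- simulate_breath_hold(tr, 40, hold_amplitude = 0,
                                   channel_labels = labs)
  expect_identical(zero_amp$raw$data, base$raw$data)
  held <- simulate_breath_hold(tr, 40, channel_labels = labs)
  exc <- held$raw$data - base$raw$data
  # identical excursion on every channel
  for (ch in 2:4) expect_equal(exc[ch, ], exc[1, ], tolerance = 1e-12)
  expect_lt(min(exc), -0.02)
  expect_error(simulate_breath_hold(tr, c(30, 35), channel_labels = labs),
               "overlap")
  expect_error(simulate_breath_hold(tr, 1000, channel_labels = labs),
               "within the recording span")
})

test_that("null cohort is reproducible, task-free noise", {
  coh <- make_null_cohort(10, seed = 1)
  expect_length(coh, 10)
  coh2 <- make_null_cohort(10, seed = 1)
  expect_identical(lapply(coh, function(s) s$raw$data),
                   lapply(coh2, function(s) s$raw$data))
  # different subjects get different noise
  expect_false(identical(coh[[1]]$raw$data, coh[[2]]$raw$data))
})
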