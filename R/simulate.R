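#' Ground truth for a simulated auditory brainstem response
#'
#' Describes, per stimulus intensity, the latencies and amplitudes of Jewett
#' waves I, III and V plus the additive noise level. Defaults follow the
#' canonical level dependence of the click-evoked ABR: amplitudes grow and
#' latencies shrink as intensity rises, with all latencies inside the
#' clinical scoring windows (I: 1.6-3.5 ms, III: 3.6-5.5 ms, V: 5.6-8.0 ms).
#' The default noise (10 uV RMS) gives a per-trial wave-V SNR of about 0.1
#' at 90 dB SPL, typical of raw single-sweep ABR recordings.
#'
#' @param intensities Stimulus levels, dB SPL.
#' @param latencies_ms 3 x length(intensities) matrix of wave I/III/V
#'   latencies in ms (rows named I, III, V).
#' @param amplitudes 3 x length(intensities) matrix of wave amplitudes, uV.
#' @param noise_sd Additive white-noise standard deviation, uV.
#' @param wave_width_ms Full width at half maximum of each Gaussian wave
#'   template, ms.
#' @param seed Integer seed; the simulator is a pure function of
#'   (parameters, seed).
#' @return An object of class `abr_truth`.
#' @export
abr_truth <- function(intensities = c(50, 70, 90),
                      latencies_ms = cbind(`50` = c(2.8, 4.8, 7.4),
                                           `70` = c(2.4, 4.4, 6.6),
                                           `90` = c(2.0, 4.0, 6.0)),
                      amplitudes = cbind(`50` = c(0.10, 0.22, 0.45),
                                         `70` = c(0.15, 0.30, 0.70),
                                         `90` = c(0.20, 0.40, 1.00)),
                      noise_sd = 10,
                      wave_width_ms = 0.4,
                      seed = 1L) {
  latencies_ms <- as.matrix(latencies_ms)
  amplitudes <- as.matrix(amplitudes)
  stopifnot(nrow(latencies_ms) == 3L, nrow(amplitudes) == 3L,
            ncol(latencies_ms) == length(intensities),
            ncol(amplitudes) == length(intensities),
            noise_sd >= 0, wave_width_ms > 0)
  rownames(latencies_ms) <- rownames(amplitudes) <- c("I", "III", "V")
  colnames(latencies_ms) <- colnames(amplitudes) <- as.character(intensities)
  win <- abr_windows()
  for (w in c("I", "III", "V")) {
    lo <- win[[w]][1]; hi <- win[[w]][2]
    if (any(latencies_ms[w, ] < lo | latencies_ms[w, ] > hi))
      stop("wave ", w, " latencies must lie in its scoring window [",
           lo, ", ", hi, "] ms")
  }
  if (any(apply(latencies_ms, 2, is.unsorted)))
    stop("latencies must be non-decreasing I -> III -> V")
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0")
  structure(list(intensities = intensities, latencies_ms = latencies_ms,
                 amplitudes = amplitudes, noise_sd = noise_sd,
                 wave_width_ms = wave_width_ms, seed = as.integer(seed)),
            class = "abr_truth")
}

#' Default ABR scoring windows (ms)
#' @return Named list of c(lo, hi) latency windows for waves I, III, V.
#' @export
abr_windows <- function() {
  list(I = c(1.6, 3.5), III = c(3.6, 5.5), V = c(5.6, 8.0))
}

#' Simulate a click-evoked EEG recording with known ABR ground truth
#'
#' Every click in the protocol adds a deterministic template - the sum of
#' three Gaussian bumps at the true wave I/III/V latencies and amplitudes for
#' that click's intensity - to each channel; responses to successive clicks
#' superpose linearly. Independent white Gaussian noise of standard deviation
#' `truth$noise_sd` is then added per channel. A silent pre-roll is inserted
#' before the first click so that a continuous pre-stimulus baseline exists.
#'
#' @param protocol A click `stimulus_protocol` (see [build_click_protocol()]).
#' @param truth An [abr_truth()]. Every intensity in the protocol must be
#'   present in the truth.
#' @param n_channels Number of EEG channels to generate.
#' @param sample_rate EEG sample rate, Hz; must be at least 10 kHz so 0.1-ms
#'   scale features are resolved.
#' @param pre_s Silent pre-roll before the first click, seconds.
#' @param post_s Padding after the last click, seconds.
#' @return A `time_series_recording` (modality `"eeg"`, units uV) whose
#'   events are the protocol events shifted by `pre_s`.
#' @export
simulate_abr <- function(protocol, truth, n_channels = 1L,
                         sample_rate = 16000, pre_s = 1, post_s = 0.1) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(truth, "abr_truth"))
  if (sample_rate < 10000)
    stop("sample_rate must be >= 10 kHz to resolve 0.1-ms features")
  ev <- stimulus_events(protocol)
  if (nrow(ev) && !all(ev$kind == "click"))
    stop("simulate_abr expects a click protocol")
  missing_int <- setdiff(unique(ev$intensity), truth$intensities)
  if (length(missing_int))
    stop("protocol intensities absent from truth: ",
         paste(missing_int, collapse = ", "))

  dur <- pre_s + protocol$total_duration + post_s
  n <- ceiling(dur * sample_rate)
  clean <- numeric(n)
  # one 12-ms template per intensity, sum of three Gaussian bumps
  tpl_len <- ceiling(0.012 * sample_rate)
  tpl_t_ms <- (seq_len(tpl_len) - 1L) / sample_rate * 1000
  sd_ms <- truth$wave_width_ms / (2 * sqrt(2 * log(2)))
  templates <- lapply(as.character(truth$intensities), function(key) {
    lat <- truth$latencies_ms[, key]
    amp <- truth$amplitudes[, key]
    tpl <- numeric(tpl_len)
    for (w in 1:3)
      tpl <- tpl + amp[w] * exp(-0.5 * ((tpl_t_ms - lat[w]) / sd_ms)^2)
    tpl
  })
  names(templates) <- as.character(truth$intensities)
  if (nrow(ev)) {
    start_idx <- round((ev$onset + pre_s) * sample_rate) + 1L
    for (i in seq_len(nrow(ev))) {
      j <- start_idx[i]:min(start_idx[i] + tpl_len - 1L, n)
      clean[j] <- clean[j] + templates[[as.character(ev$intensity[i])]][seq_along(j)]
    }
  }
  set.seed(truth$seed)
  data <- matrix(rep(clean, each = n_channels), nrow = n_channels)
  if (truth$noise_sd > 0)
    data <- data + matrix(stats::rnorm(n_channels * n, sd = truth$noise_sd),
                          nrow = n_channels)
  ev_shift <- protocol$events
  ev_shift$onset <- ev_shift$onset + pre_s
  time_series_recording(data, sample_rate,
                        channel_labels = sprintf("EEG%02d", seq_len(n_channels)),
                        events = ev_shift, modality = "eeg")
}

#' Ground truth for simulated fNIRS hemodynamics
#'
#' Describes the task response and nuisance structure of a raw-intensity
#' fNIRS recording: per-channel fractional response amplitudes (negative
#' values are intensity decreases, the expected signature of increased
#' absorption), the trough latency of the response, shared systemic
#' oscillations (cardiac ~1.1 Hz, respiratory ~0.3 Hz, vasomotor ~0.1 Hz),
#' a linear drift and white noise. Default response amplitudes are
#' heterogeneous across eight channels at the few-percent scale; defaults for
#' the nuisance terms are typical of continuous-wave optical recordings
#' (cardiac pulsation ~0.5% of mean intensity, slower waves ~0.3%).
#'
#' @param channel_betas Fractional response amplitude per channel (negative =
#'   intensity decrease); a zero entry is a valid null channel.
#' @param trough_latency Seconds from stimulus onset to the response trough;
#'   default 12 s (midpoint of the expected 10-15 s range).
#' @param response_duration Approximate support of the response, seconds
#'   (kernel is evaluated over this span times two).
#' @param cardiac_amp,respiratory_amp,vasomotor_amp Fractional amplitudes of
#'   the shared systemic sinusoids.
#' @param cardiac_freq,respiratory_freq,vasomotor_freq Their frequencies, Hz.
#' @param drift_slope Linear drift, fraction of baseline per second.
#' @param noise_sd White-noise standard deviation, fraction of baseline.
#' @param baseline Mean raw intensity level, arbitrary units.
#' @param chromo_noise_sd White-noise level on the chromophore traces, uM.
#' @param seed Integer seed.
#' @return An object of class `hemo_truth`.
#' @export
hemo_truth <- function(channel_betas = c(-0.008, -0.014, -0.023, -0.017,
                                         -0.010, -0.019, -0.012, -0.006),
                       trough_latency = 12,
                       response_duration = 20,
                       cardiac_amp = 0.005, cardiac_freq = 1.1,
                       respiratory_amp = 0.003, respiratory_freq = 0.3,
                       vasomotor_amp = 0.003, vasomotor_freq = 0.1,
                       drift_slope = 1e-4,
                       noise_sd = 0.005,
                       baseline = 1,
                       chromo_noise_sd = 0.05,
                       seed = 1L) {
  stopifnot(all(is.finite(channel_betas)), trough_latency >= 5,
            trough_latency <= 20, response_duration > 0, baseline > 0,
            noise_sd >= 0, chromo_noise_sd >= 0)
  structure(list(channel_betas = channel_betas,
                 trough_latency = trough_latency,
                 response_duration = response_duration,
                 cardiac_amp = cardiac_amp, cardiac_freq = cardiac_freq,
                 respiratory_amp = respiratory_amp,
                 respiratory_freq = respiratory_freq,
                 vasomotor_amp = vasomotor_amp, vasomotor_freq = vasomotor_freq,
                 drift_slope = drift_slope, noise_sd = noise_sd,
                 baseline = baseline, chromo_noise_sd = chromo_noise_sd,
                 seed = as.integer(seed)),
            class = "hemo_truth")
}

#' Unimodal hemodynamic response kernel
#'
#' Gamma-density shaped kernel normalized to peak 1, with its mode at
#' `trough_latency` seconds. Multiplied by a negative amplitude it models the
#' slow task-locked intensity decrease that troughs 10-15 s after stimulus
#' onset and returns gradually to baseline.
#'
#' @param t Time since stimulus onset, seconds (values < 0 give 0).
#' @param trough_latency Mode of the kernel, seconds.
#' @param shape Gamma shape parameter (default 4).
#' @return Kernel values in [0, 1].
#' @export
hemo_kernel <- function(t, trough_latency = 12, shape = 4) {
  stopifnot(shape > 1, trough_latency > 0)
  rate <- (shape - 1) / trough_latency
  peak <- stats::dgamma(trough_latency, shape = shape, rate = rate)
  out <- ifelse(t < 0, 0, stats::dgamma(t, shape = shape, rate = rate) / peak)
  out
}

# Sum of response kernels over all warble onsets, sampled on the recording grid.
response_trace <- function(onsets, n, sample_rate, trough_latency, shape = 4) {
  t <- (seq_len(n) - 1L) / sample_rate
  r <- numeric(n)
  for (on in onsets) r <- r + hemo_kernel(t - on, trough_latency, shape)
  r
}

#' Simulate a raw-intensity fNIRS recording plus paired chromophores
#'
#' Raw intensity per channel is
#' `baseline * (1 + beta_ch * r(t) + systemic(t) + drift(t)) + noise`, where
#' `r(t)` is a positive unimodal kernel peaking `trough_latency` seconds
#' after each warble onset (so a negative `beta_ch` produces the expected
#' task-locked intensity decrease), and `systemic(t)` is a sum of cardiac,
#' respiratory and vasomotor sinusoids with seeded random phases shared by
#' all channels. The paired chromophore recording carries, per channel, a
#' Delta-HbO rise and a smaller Delta-HbR dip whose sum (Delta-HbT, stored
#' explicitly) increases with the response; HbT equals HbO + HbR exactly.
#'
#' @param protocol A `stimulus_protocol`; warble events drive the response.
#' @param truth A [hemo_truth()]; `channel_betas` must match the number of
#'   channels.
#' @param channel_labels Channel (source-detector pair) labels.
#' @param sample_rate Effective sample rate, Hz (>= 2).
#' @return List with elements `raw` (modality `"fnirs_raw"`) and
#'   `chromophore` (modality `"fnirs_chromophore"`, channels labelled
#'   `"<site> HbO"`, `"<site> HbR"`, `"<site> HbT"`, units uM).
#' @export
simulate_fnirs <- function(protocol, truth,
                           channel_labels = sprintf("S%d-D%d",
                                                    rep(1:4, each = 2), 1:2),
                           sample_rate = 10) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(truth, "hemo_truth"))
  if (sample_rate < 2) stop("sample_rate must be >= 2 Hz")
  if (length(channel_labels) == 0L) stop("channel list must be non-empty")
  n_ch <- length(channel_labels)
  if (length(truth$channel_betas) != n_ch)
    stop("length(truth$channel_betas) must equal the number of channels")
  n <- ceiling(protocol$total_duration * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  onsets <- stimulus_events(protocol)$onset

  set.seed(truth$seed)
  phases <- stats::runif(3, 0, 2 * pi)
  systemic <- truth$cardiac_amp * sin(2 * pi * truth$cardiac_freq * t + phases[1]) +
    truth$respiratory_amp * sin(2 * pi * truth$respiratory_freq * t + phases[2]) +
    truth$vasomotor_amp * sin(2 * pi * truth$vasomotor_freq * t + phases[3])
  r <- response_trace(onsets, n, sample_rate, truth$trough_latency)
  drift <- truth$drift_slope * t

  raw <- matrix(0, nrow = n_ch, ncol = n)
  for (ch in seq_len(n_ch))
    raw[ch, ] <- truth$baseline *
      (1 + truth$channel_betas[ch] * r + systemic + drift)
  if (truth$noise_sd > 0)
    raw <- raw + matrix(stats::rnorm(n_ch * n,
                                     sd = truth$baseline * truth$noise_sd),
                        nrow = n_ch)

  # chromophores: HbO rise, HbR dip of a quarter the magnitude, per unit of
  # (negative) fractional intensity response; 40 uM HbO per unit |beta|.
  hbo <- matrix(0, nrow = n_ch, ncol = n)
  hbr <- matrix(0, nrow = n_ch, ncol = n)
  for (ch in seq_len(n_ch)) {
    hbo[ch, ] <- (-truth$channel_betas[ch]) * 40 * r
    hbr[ch, ] <- -0.25 * hbo[ch, ]
  }
  if (truth$chromo_noise_sd > 0) {
    hbo <- hbo + matrix(stats::rnorm(n_ch * n, sd = truth$chromo_noise_sd),
                        nrow = n_ch)
    hbr <- hbr + matrix(stats::rnorm(n_ch * n, sd = truth$chromo_noise_sd / 4),
                        nrow = n_ch)
  }
  hbt <- hbo + hbr

  raw_rec <- time_series_recording(raw, sample_rate, channel_labels,
                                   events = protocol, modality = "fnirs_raw")
  chrom <- rbind(hbo, hbr, hbt)
  chrom_labels <- c(paste(channel_labels, "HbO"),
                    paste(channel_labels, "HbR"),
                    paste(channel_labels, "HbT"))
  chrom_rec <- time_series_recording(chrom, sample_rate, chrom_labels,
                                     events = protocol,
                                     modality = "fnirs_chromophore")
  list(raw = raw_rec, chromophore = chrom_rec)
}

#' Simulate a recording with uniform breath-hold excursions
#'
#' Builds the same recording as [simulate_fnirs()] and then adds, for each
#' breath hold, a slow intensity excursion that is identical on every channel
#' (a global systemic event). Downstream, the spatial repeated-measures ANOVA
#' should classify such a uniform excursion as non-specific, in contrast to
#' the channel-heterogeneous task response.
#'
#' @param truth A [hemo_truth()].
#' @param hold_onsets Breath-hold onsets, seconds; holds must not overlap.
#' @param protocol A `stimulus_protocol` giving timing and total duration.
#' @param hold_amplitude Fractional intensity excursion at the hold trough
#'   (default -0.03, i.e. a 3% dip); 0 adds nothing.
#' @param hold_duration Approximate duration of each excursion, seconds;
#'   its trough occurs `hold_duration / 2` after hold onset.
#' @param channel_labels,sample_rate As in [simulate_fnirs()].
#' @return List with `raw` and `chromophore` recordings.
#' @export
simulate_breath_hold <- function(truth, hold_onsets = numeric(0),
                                 protocol = build_warble_protocol(),
                                 hold_amplitude = -0.03,
                                 hold_duration = 15,
                                 channel_labels = sprintf("S%d-D%d",
                                                          rep(1:4, each = 2), 1:2),
                                 sample_rate = 10) {
  if (length(hold_onsets) > 1L) {
    o <- sort(hold_onsets)
    if (any(diff(o) < hold_duration)) stop("breath holds must not overlap")
  }
  if (length(hold_onsets) &&
      any(hold_onsets < 0 | hold_onsets > protocol$total_duration))
    stop("holds must lie within the recording span")
  out <- simulate_fnirs(protocol, truth, channel_labels, sample_rate)
  if (length(hold_onsets) == 0L || hold_amplitude == 0) return(out)
  n <- n_samples(out$raw)
  exc <- hold_amplitude *
    response_trace(hold_onsets, n, sample_rate, hold_duration / 2)
  out$raw$data <- out$raw$data +
    matrix(rep(truth$baseline * exc, each = nrow(out$raw$data)),
           nrow = nrow(out$raw$data))
  # chromophores see the same global event (HbO/HbR in the usual 4:-1 ratio,
  # added uniformly so the HbO + HbR = HbT identity is preserved)
  n_site <- length(channel_labels)
  hbo_add <- (-hold_amplitude) * 40 * response_trace(hold_onsets, n,
                                                     sample_rate,
                                                     hold_duration / 2)
  add <- rbind(matrix(rep(hbo_add, each = n_site), nrow = n_site),
               matrix(rep(-0.25 * hbo_add, each = n_site), nrow = n_site),
               matrix(rep(0.75 * hbo_add, each = n_site), nrow = n_site))
  out$chromophore$data <- out$chromophore$data + add
  out
}

#' Generate a null cohort of task-free fNIRS recordings
#'
#' All response amplitudes are zero, so any positive finding downstream is a
#' false positive; systemic oscillations, drift and noise are retained.
#' Used to measure the type-I error surface of the statistical battery.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; subject s uses seed `seed * 1000 + s`.
#' @param protocol Timing protocol (default the 92-s warble block design).
#' @param truth Template [hemo_truth()]; its `channel_betas` are zeroed.
#' @param channel_labels,sample_rate As in [simulate_fnirs()].
#' @return List of per-subject lists with `raw` and `chromophore`.
#' @export
make_null_cohort <- function(n_subjects, seed = 1L,
                             protocol = build_warble_protocol(),
                             truth = hemo_truth(),
                             channel_labels = sprintf("S%d-D%d",
                                                      rep(1:4, each = 2), 1:2),
                             sample_rate = 10) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(s) {
    tr <- truth
    tr$channel_betas <- rep(0, length(channel_labels))
    tr$seed <- as.integer(seed * 1000 + s)
    simulate_fnirs(protocol, tr, channel_labels, sample_rate)
  })
}

#' Simulate a task cohort for the warble paradigm
#'
#' Each subject shares the template response topography but with an
#' individual multiplicative gain (log-normal, sd `subject_gain_sd` on the
#' log scale) and an independent noise realization, emulating between-subject
#' variability in response amplitude.
#'
#' @param n_subjects Number of subjects (default 34, the warble cohort size).
#' @param seed Integer seed.
#' @param truth Template [hemo_truth()].
#' @param subject_gain_sd SD of the per-subject log gain (default 0.2).
#' @param protocol,channel_labels,sample_rate As in [simulate_fnirs()].
#' @return List of per-subject lists with `raw` and `chromophore`.
#' @export
simulate_warble_cohort <- function(n_subjects = 34, seed = 1L,
                                   truth = hemo_truth(),
                                   subject_gain_sd = 0.2,
                                   protocol = build_warble_protocol(),
                                   channel_labels = sprintf("S%d-D%d",
                                                            rep(1:4, each = 2),
                                                            1:2),
                                   sample_rate = 10) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  gains <- exp(stats::rnorm(n_subjects, sd = subject_gain_sd))
  lapply(seq_len(n_subjects), function(s) {
    tr <- truth
    tr$channel_betas <- truth$channel_betas * gains[s]
    tr$seed <- as.integer(seed * 1000 + s)
    simulate_fnirs(protocol, tr, channel_labels, sample_rate)
  })
}
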