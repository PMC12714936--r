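# End-to-end runners chaining simulation -> pipelines -> report tables,
# with seeded reproducibility.

shift_protocol <- function(protocol, by) {
  ev <- protocol$events
  ev$onset <- ev$onset + by
  new_protocol(ev, total_duration = protocol$total_duration + 2 * by,
               repetition_rate = protocol$repetition_rate)
}

#' Configuration for the click (ABR) study runner
#'
#' Defaults reproduce the click paradigm's stated design: 20 subjects, 38
#' EEG channels, 1000 clicks per intensity at 81.9 Hz for 50/70/90 dB SPL,
#' 100-3000 Hz band-pass, 12-ms epochs, 0.5-s pre-block baseline.
#'
#' @param n_subjects,n_channels,clicks_per_intensity,intensities,rate
#'   Cohort and protocol parameters.
#' @param sample_rate EEG simulation rate, Hz.
#' @param filter_low,filter_high Band-pass cutoffs, Hz.
#' @param epoch_ms,baseline_s Epoching parameters.
#' @param normative Normative wave latencies, ms.
#' @param latency_jitter_sd Between-subject latency jitter, ms.
#' @param amplitude_gain_sd Between-subject log-amplitude gain SD.
#' @param include_fnirs Simulate the paired fNIRS recording and the
#'   cross-modal comparison (default TRUE).
#' @param fnirs_sites Site labels for the paired fNIRS channels.
#' @param fnirs_betas Fractional response amplitudes for those sites.
#' @param seed Master seed.
#' @return A named list of class `study1_config`.
#' @export
study1_config <- function(n_subjects = 20, n_channels = 38,
                          clicks_per_intensity = 1000,
                          intensities = c(50, 70, 90), rate = 81.9,
                          sample_rate = 16000,
                          filter_low = 100, filter_high = 3000,
                          epoch_ms = 12, baseline_s = 0.5,
                          normative = c(I = 1.6, III = 3.8, V = 5.6),
                          latency_jitter_sd = 0.1,
                          amplitude_gain_sd = 0.2,
                          include_fnirs = TRUE,
                          fnirs_sites = c("S1-D1", "S2-D2"),
                          fnirs_betas = c(-0.02, -0.015),
                          seed = 1L) {
  structure(as.list(environment()), class = "study1_config")
}

#' Run the click (ABR) study end to end
#'
#' For each simulated subject: generate the click EEG recording, band-pass
#' filter, epoch into per-channel/per-intensity groups, average and
#' normalize, score Jewett waves, compute latency deviations and SNR; if
#' enabled, generate the paired fNIRS recording, extract the Delta-HbT trace
#' on the same epoch timeline, and compute the cross-modal correlation. The
#' run is deterministic for a fixed seed.
#'
#' @param config A [study1_config()].
#' @return A list bundle with `waveforms` (all averaged waveforms),
#'   `scores` (per subject/channel/intensity wave table), `snr_table`
#'   (per-intensity mean and best-channel SNR), `crossmodal` (per
#'   subject/site/intensity r and lag), `tables` (report-ready data
#'   frames) and a `manifest` of counts.
#' @export
run_study1 <- function(config = study1_config()) {
  stopifnot(inherits(config, "study1_config"))
  cf <- config
  protocol <- build_click_protocol(cf$rate, cf$clicks_per_intensity,
                                   cf$intensities)
  base_truth <- abr_truth()
  win <- abr_windows()
  waveforms <- list()
  score_rows <- list()
  cm_rows <- list()
  for (s in seq_len(cf$n_subjects)) {
    sub_seed <- as.integer(cf$seed * 1000 + s)
    set.seed(sub_seed)
    jit <- stats::rnorm(3, sd = cf$latency_jitter_sd)
    gain <- exp(stats::rnorm(1, sd = cf$amplitude_gain_sd))
    lat <- base_truth$latencies_ms + jit  # same shift at all intensities
    for (w in 1:3) {  # keep jittered latencies inside the scoring windows
      lim <- win[[w]]
      lat[w, ] <- pmin(pmax(lat[w, ], lim[1] + 0.1), lim[2] - 0.1)
    }
    lat <- apply(lat, 2, sort)  # preserve I -> III -> V ordering
    truth <- abr_truth(latencies_ms = lat,
                       amplitudes = base_truth$amplitudes * gain,
                       noise_sd = base_truth$noise_sd, seed = sub_seed)
    rec <- simulate_abr(protocol, truth, n_channels = cf$n_channels,
                        sample_rate = cf$sample_rate)
    rec <- bandpass(rec, cf$filter_low, cf$filter_high)
    es <- epoch_clicks(rec, epoch_ms = cf$epoch_ms,
                       baseline_s = cf$baseline_s)
    wfs <- average_and_normalize(es)
    fn_wfs <- NULL
    if (cf$include_fnirs) {
      fn_truth <- hemo_truth(channel_betas = cf$fnirs_betas,
                             seed = sub_seed)
      fn <- simulate_fnirs(shift_protocol(protocol, 5), fn_truth,
                           channel_labels = cf$fnirs_sites)
      fn_wfs <- fnirs_click_trace(fn$chromophore,
                                  epoch_ms = cf$epoch_ms,
                                  target_rate = cf$sample_rate)
    }
    for (wf in wfs) {
      waveforms[[length(waveforms) + 1L]] <- wf
      sc <- detect_waves(wf)
      dev <- latency_deviation(sc, cf$normative)
      snr_val <- tryCatch(snr(wf), error = function(e) NA_real_)
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        subject = s, channel = wf$channel, intensity = wf$intensity,
        wave = sc$waves$wave, present = sc$waves$present,
        latency_ms = sc$waves$latency_ms,
        amplitude = sc$waves$amplitude,
        deviation_ms = dev$deviation_ms,
        snr = snr_val)
    }
    if (cf$include_fnirs) {
      # compare the first EEG channel against each fNIRS site, per intensity
      for (fw in fn_wfs) {
        ew <- Filter(function(w) w$channel == rec$channel_labels[1] &&
                                 w$intensity == fw$intensity, wfs)[[1]]
        cm <- tryCatch(crossmodal_correlation(ew, fw),
                       error = function(e) list(r = NA_real_,
                                                lag_ms = NA_real_))
        cm_rows[[length(cm_rows) + 1L]] <- data.frame(
          subject = s, site = fw$channel, intensity = fw$intensity,
          r = cm$r, lag_ms = cm$lag_ms)
      }
    }
  }
  scores <- do.call(rbind, score_rows)
  crossmodal <- if (length(cm_rows)) do.call(rbind, cm_rows) else NULL
  snr_per_wf <- unique(scores[, c("subject", "channel", "intensity", "snr")])
  snr_table <- do.call(rbind, lapply(split(snr_per_wf, snr_per_wf$intensity),
    function(d) data.frame(intensity = d$intensity[1],
                           mean_snr = mean(d$snr, na.rm = TRUE),
                           best_snr = max(d$snr, na.rm = TRUE))))
  rownames(snr_table) <- NULL
  manifest <- list(n_subjects = cf$n_subjects,
                   n_channels = cf$n_channels,
                   n_intensities = length(cf$intensities),
                   datasets_per_subject = cf$n_channels * length(cf$intensities),
                   n_waveforms = length(waveforms))
  tables <- list(wave_scores = scores, snr = snr_table)
  if (!is.null(crossmodal)) tables$crossmodal <- crossmodal
  list(waveforms = waveforms, scores = scores, snr_table = snr_table,
       crossmodal = crossmodal, tables = tables, manifest = manifest,
       config = cf)
}

#' Configuration for the warble (block-design) study runner
#'
#' Defaults reproduce the warble paradigm's stated design: 34 subjects,
#' eight optode channels at 10 Hz, the fixed 92-s block protocol, 200-ms
#' moving-average smoothing, a hemodynamic kernel troughing 12 s after
#' onset, and alpha = 0.05.
#'
#' @param n_subjects Cohort size.
#' @param channel_labels Source-detector channel labels.
#' @param sample_rate Effective fNIRS rate, Hz.
#' @param truth Template [hemo_truth()] for the simulated cohort.
#' @param subject_gain_sd Between-subject log-gain SD.
#' @param smooth_ms Moving-average window, ms.
#' @param trough_latency,kernel_shape Hemodynamic kernel parameters.
#' @param window,baseline Epoch window and baseline, seconds from onset.
#' @param alpha Significance level.
#' @param seed Master seed.
#' @return A named list of class `study2_config`.
#' @export
study2_config <- function(n_subjects = 34,
                          channel_labels = sprintf("S%d-D%d",
                                                   rep(1:4, each = 2), 1:2),
                          sample_rate = 10,
                          truth = hemo_truth(),
                          subject_gain_sd = 0.2,
                          smooth_ms = 200,
                          trough_latency = 12, kernel_shape = 4,
                          window = c(-5, 15), baseline = c(-5, 0),
                          alpha = 0.05,
                          seed = 1L) {
  structure(as.list(environment()), class = "study2_config")
}

#' Run the warble (block-design) study end to end
#'
#' Simulates the cohort, then runs the full battery on the raw-intensity
#' data: percent-change epoching and grand average with SEM, PCA of the
#' pooled epochs, per-subject task GLM followed by group inference with FDR
#' correction, time-locked cross-correlation with group inference, the
#' stimulation-versus-silence contrast matrices on Delta-HbT with pooled
#' p-value histogram, and the spatial repeated-measures ANOVA with
#' Holm-corrected post-hoc pairs. Deterministic for a fixed seed.
#'
#' @param config A [study2_config()].
#' @param cohort Optional pre-simulated cohort (list of `raw`/`chromophore`
#'   pairs); by default one is simulated from the config.
#' @return A list bundle with `grand` (mean + SEM), `pca`, `betas`
#'   (subjects x channels), `glm_table`, `crosscorr_table`, `contrast`,
#'   `p_hist`, `anova`, `tables` (report-ready data frames) and `manifest`.
#' @export
run_study2 <- function(config = study2_config(), cohort = NULL) {
  stopifnot(inherits(config, "study2_config"))
  cf <- config
  protocol <- build_warble_protocol()
  if (is.null(cohort))
    cohort <- simulate_warble_cohort(cf$n_subjects, seed = cf$seed,
                                     truth = cf$truth,
                                     subject_gain_sd = cf$subject_gain_sd,
                                     protocol = protocol,
                                     channel_labels = cf$channel_labels,
                                     sample_rate = cf$sample_rate)
  n_subj <- length(cohort)
  C <- length(cf$channel_labels)
  betas <- matrix(NA_real_, n_subj, C)
  peak_r <- matrix(NA_real_, n_subj, C)
  peak_cov <- matrix(NA_real_, n_subj, C)
  all_epochs <- list()
  contrasts <- list()
  n_samp <- NULL
  pos_reg <- NULL
  for (s in seq_len(n_subj)) {
    raw <- smooth_series(cohort[[s]]$raw, window_ms = cf$smooth_ms)
    fit <- glm_task(raw, protocol, trough_latency = cf$trough_latency,
                    shape = cf$kernel_shape)
    betas[s, ] <- fit$channels$beta
    if (is.null(pos_reg)) {
      n_samp <- ncol(raw$data)
      pos_reg <- task_regressor(protocol, cf$sample_rate, n_samp,
                                cf$trough_latency, cf$kernel_shape,
                                negative = FALSE)
    }
    frac <- raw$data / rowMeans(raw$data) - 1
    rownames(frac) <- cf$channel_labels
    cc <- crosscorr_task(frac, pos_reg, cf$sample_rate)
    peak_r[s, ] <- cc$peak_r
    peak_cov[s, ] <- cc$peak_cov
    all_epochs[[s]] <- epoch_blocks(raw, window = cf$window,
                                    baseline = cf$baseline)
    hbt <- chromophore(cohort[[s]]$chromophore, "HbT")
    contrasts[[s]] <- stim_silence_contrast(
      hbt, onsets = protocol$events$onset[protocol$events$kind != "silence"],
      alpha = cf$alpha, sample_rate = cf$sample_rate)
  }
  pooled <- do.call(rbind, lapply(all_epochs, `[[`, "epochs"))
  grand <- grand_average(pooled)
  grand$time_s <- all_epochs[[1]]$time_s
  pca <- pca_epochs(pooled, n_components = 5)
  pca$time_s <- all_epochs[[1]]$time_s
  glm_table <- glm_group(betas, alpha = cf$alpha)
  cc_table <- crosscorr_group(peak_r, peak_cov, alpha = cf$alpha)
  contrast <- contrast_average(contrasts, alpha = cf$alpha)
  p_hist <- p_histogram(contrast$p_values)
  anova <- spatial_anova(betas)
  anova_table <- data.frame(effect = "Channel", F_value = anova$F_value,
                            df_num = anova$df_num, df_den = anova$df_den,
                            p_value = anova$p_value)
  tables <- list(glm = glm_table, crosscorr = cc_table,
                 anova = anova_table,
                 posthoc = as.data.frame(anova$posthoc),
                 p_histogram = p_hist,
                 contrast_r = as.data.frame(contrast$r_matrix),
                 contrast_p = as.data.frame(contrast$p_matrix))
  manifest <- list(n_subjects = n_subj, n_channels = C,
                   n_epochs = nrow(pooled),
                   pc1_explained = pca$explained[1])
  list(grand = grand, pca = pca, betas = betas, peak_r = peak_r,
       peak_cov = peak_cov, glm_table = glm_table,
       crosscorr_table = cc_table, contrast = contrast, p_hist = p_hist,
       anova = anova, tables = tables, manifest = manifest, config = cf)
}
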