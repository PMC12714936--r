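# Click-ABR pipeline: band-pass filtering, epoching, averaging, Jewett-wave
# scoring, SNR, and EEG-fNIRS cross-modal correlation.

#' Zero-phase band-pass filter a recording
#'
#' 4th-order Butterworth applied forward and backward per channel
#' (zero phase), so peak latencies are not biased by group delay.
#'
#' @param rec A `time_series_recording`.
#' @param low High-pass cutoff, Hz (default 100).
#' @param high Low-pass cutoff, Hz (default 3000).
#' @param order Filter order (default 4).
#' @return The filtered recording (same length, same events).
#' @export
bandpass <- function(rec, low = 100, high = 3000, order = 4) {
  stopifnot(inherits(rec, "time_series_recording"), low > 0, high > low)
  if (rec$sample_rate <= 2 * high)
    stop("sample_rate must exceed twice the low-pass cutoff")
  bf <- signal::butter(order, c(low, high) / (rec$sample_rate / 2),
                       type = "pass")
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- signal::filtfilt(bf, rec$data[ch, ])
  out
}

# contiguous intensity blocks in event order: returns data.frame
# (intensity, first_onset)
intensity_blocks <- function(events) {
  ev <- events[events$kind != "silence", , drop = FALSE]
  if (!nrow(ev)) return(data.frame(intensity = numeric(0), first_onset = numeric(0)))
  ev <- ev[order(ev$onset), , drop = FALSE]
  new_block <- c(TRUE, ev$intensity[-1] != ev$intensity[-nrow(ev)])
  data.frame(intensity = ev$intensity[new_block],
             first_onset = ev$onset[new_block])
}

#' Segment a click recording into per-channel, per-intensity epochs
#'
#' Cuts one fixed-length epoch per click, starting at the click onset
#' (t = 0, no pre-stimulus samples inside the epoch), and groups epochs by
#' stimulus intensity and channel. Baseline statistics for each group are
#' taken from the continuous signal immediately preceding that intensity
#' block (`baseline_s` seconds), since an epoch shorter than the
#' inter-stimulus interval cannot contain its own pre-stimulus baseline.
#' Epochs that would extend past the end of the recording are dropped and
#' counted.
#'
#' @param rec A `time_series_recording` carrying click events (typically
#'   already band-passed).
#' @param epoch_ms Epoch length, ms (default 12).
#' @param baseline_s Continuous pre-block baseline length, seconds
#'   (default 0.5).
#' @return An object of class `epoch_set`: a list of groups, each with the
#'   trial x sample epoch matrix, channel, intensity, baseline mean/sd and
#'   dropped-epoch count.
#' @export
epoch_clicks <- function(rec, epoch_ms = 12, baseline_s = 0.5) {
  stopifnot(inherits(rec, "time_series_recording"))
  fs <- rec$sample_rate
  nsamp <- round(epoch_ms / 1000 * fs)
  ev <- rec$events[rec$events$kind != "silence", , drop = FALSE]
  groups <- list()
  n_dropped_total <- 0L
  if (nrow(ev)) {
    blocks <- intensity_blocks(rec$events)
    n <- ncol(rec$data)
    for (b in seq_len(nrow(blocks))) {
      int <- blocks$intensity[b]
      onsets <- ev$onset[ev$intensity == int]
      start_idx <- round(onsets * fs) + 1L
      keep <- start_idx + nsamp - 1L <= n
      n_dropped <- sum(!keep)
      n_dropped_total <- n_dropped_total + n_dropped * nrow(rec$data)
      start_idx <- start_idx[keep]
      b0 <- round((blocks$first_onset[b] - baseline_s) * fs) + 1L
      b1 <- round(blocks$first_onset[b] * fs)
      b0 <- max(1L, b0)
      idx_mat <- outer(start_idx, 0:(nsamp - 1L), `+`)
      for (ch in seq_len(nrow(rec$data))) {
        x <- rec$data[ch, ]
        epochs <- matrix(x[idx_mat], nrow = length(start_idx))
        base <- if (b1 >= b0) x[b0:b1] else numeric(0)
        groups[[length(groups) + 1L]] <- list(
          channel = rec$channel_labels[ch],
          channel_index = ch,
          intensity = int,
          epochs = epochs,
          n_epochs = nrow(epochs),
          n_dropped = n_dropped,
          baseline_mean = if (length(base)) mean(base) else 0,
          baseline_sd = if (length(base) > 1L) stats::sd(base) else 0)
      }
    }
  }
  structure(list(groups = groups, epoch_ms = epoch_ms, sample_rate = fs,
                 n_dropped = n_dropped_total),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d group(s), %g ms epochs @ %g Hz, %d dropped epoch(s)\n",
              length(x$groups), x$epoch_ms, x$sample_rate, x$n_dropped))
  invisible(x)
}

new_averaged_waveform <- function(values, time_ms, channel, intensity,
                                  n_averaged, baseline_mean, baseline_sd,
                                  norm_factor, normalized, sample_rate) {
  structure(list(values = values, time_ms = time_ms, channel = channel,
                 intensity = intensity, n_averaged = n_averaged,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 norm_factor = norm_factor, normalized = normalized,
                 sample_rate = sample_rate),
            class = "averaged_waveform")
}

#' @export
print.averaged_waveform <- function(x, ...) {
  cat(sprintf("<averaged_waveform> %s @ %g dB: %d samples, n = %d%s\n",
              x$channel, x$intensity, length(x$values), x$n_averaged,
              if (x$normalized) ", normalized" else " (normalization skipped)"))
  invisible(x)
}

#' Average epochs and normalize to peak amplitude
#'
#' For every (channel, intensity) group: epochs are averaged across trials,
#' the pre-block baseline mean is subtracted, and the result is divided by
#' its maximum absolute value so the scored waveform peaks at 1. The
#' pre-normalization scale is retained in `norm_factor` together with the
#' baseline mean and SD, so the SNR can be computed on physical units. An
#' all-zero average skips normalization and sets `normalized = FALSE`.
#'
#' @param es An `epoch_set` from [epoch_clicks()].
#' @return List of `averaged_waveform` objects, one per group.
#' @export
average_and_normalize <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  lapply(es$groups, function(g) {
    if (g$n_epochs < 1L) stop("group has no epochs")
    avg <- colMeans(g$epochs) - g$baseline_mean
    nf <- max(abs(avg))
    if (nf > 0) {
      values <- avg / nf
      normalized <- TRUE
    } else {
      values <- avg
      nf <- 1
      normalized <- FALSE
    }
    new_averaged_waveform(values,
                          time_ms = (seq_along(avg) - 1L) / es$sample_rate * 1000,
                          channel = g$channel, intensity = g$intensity,
                          n_averaged = g$n_epochs,
                          baseline_mean = g$baseline_mean,
                          baseline_sd = g$baseline_sd,
                          norm_factor = nf, normalized = normalized,
                          sample_rate = es$sample_rate)
  })
}

# Local maxima above min_height with a global minimum-distance constraint:
# peaks are accepted in order of decreasing amplitude (ties: earliest), and
# a candidate closer than min_dist samples to an accepted peak is discarded.
find_peaks <- function(x, min_height, min_dist_samples) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_dist_samples))
      kept <- c(kept, i)
  }
  sort(kept)
}

#' Score Jewett waves I, III and V on an averaged waveform
#'
#' Local maxima meeting the minimum height and global minimum-distance
#' criteria are assigned to the wave scoring windows; the highest qualifying
#' peak inside each window wins (ties broken by earlier latency). Peaks not
#' assigned to any wave are reported as extra peaks. Absence of a wave is a
#' valid result, not an error. Inter-peak intervals I-III, III-V and I-V are
#' computed where both waves are present.
#'
#' @param wf A normalized `averaged_waveform`.
#' @param windows Named list of `c(lo, hi)` latency windows in ms
#'   (default [abr_windows()]).
#' @param min_height Minimum normalized peak height (default 0.08).
#' @param min_distance_ms Minimum distance between any two accepted peaks,
#'   ms, applied across the whole waveform before window assignment
#'   (default 2).
#' @return An object of class `wave_score` with elements `waves` (data frame
#'   wave/present/latency_ms/amplitude), `intervals` (named numeric), and
#'   `extra_peaks` (data frame latency_ms/amplitude).
#' @export
detect_waves <- function(wf, windows = abr_windows(), min_height = 0.08,
                         min_distance_ms = 2) {
  stopifnot(inherits(wf, "averaged_waveform"))
  dist_samples <- min_distance_ms / 1000 * wf$sample_rate
  pk <- find_peaks(wf$values, min_height, dist_samples)
  lat <- wf$time_ms[pk]
  amp <- wf$values[pk]
  assigned <- rep(FALSE, length(pk))
  waves <- data.frame(wave = names(windows), present = FALSE,
                      latency_ms = NA_real_, amplitude = NA_real_,
                      stringsAsFactors = FALSE)
  for (w in seq_along(windows)) {
    lo <- windows[[w]][1]; hi <- windows[[w]][2]
    in_win <- which(lat >= lo & lat <= hi & !assigned)
    if (length(in_win)) {
      best <- in_win[order(-amp[in_win], lat[in_win])][1]
      waves$present[w] <- TRUE
      waves$latency_ms[w] <- lat[best]
      waves$amplitude[w] <- amp[best]
      assigned[best] <- TRUE
    }
  }
  extra <- data.frame(latency_ms = lat[!assigned], amplitude = amp[!assigned])
  iv <- function(a, b) {
    ia <- match(a, waves$wave); ib <- match(b, waves$wave)
    if (!is.na(ia) && !is.na(ib) && waves$present[ia] && waves$present[ib])
      waves$latency_ms[ib] - waves$latency_ms[ia]
    else NA_real_
  }
  intervals <- c(I_III = iv("I", "III"), III_V = iv("III", "V"),
                 I_V = iv("I", "V"))
  structure(list(waves = waves, intervals = intervals, extra_peaks = extra,
                 channel = wf$channel, intensity = wf$intensity),
            class = "wave_score")
}

#' @export
print.wave_score <- function(x, ...) {
  cat(sprintf("<wave_score> %s @ %g dB\n", x$channel, x$intensity))
  print(x$waves, row.names = FALSE)
  invisible(x)
}

#' Signed latency deviation from normative values
#'
#' @param score A `wave_score`.
#' @param normative Named numeric vector of normative latencies, ms, for the
#'   scored waves (e.g. `c(I = 1.6, III = 3.8, V = 5.6)`).
#' @return Data frame with wave, measured and normative latency, and the
#'   signed deviation (measured - normative); `NA` where the wave is absent.
#' @export
latency_deviation <- function(score, normative) {
  stopifnot(inherits(score, "wave_score"))
  w <- score$waves
  miss <- setdiff(w$wave[w$present], names(normative))
  if (length(miss))
    stop("normative latency missing for wave(s): ", paste(miss, collapse = ", "))
  data.frame(wave = w$wave,
             measured_ms = w$latency_ms,
             normative_ms = unname(normative[w$wave]),
             deviation_ms = w$latency_ms - unname(normative[w$wave]))
}

#' Signal-to-noise ratio of an averaged waveform
#'
#' The ratio of the peak amplitude (relative to the baseline mean) to the
#' standard deviation of the baseline period on the averaged-waveform
#' scale. The stored baseline SD is measured on the continuous pre-block
#' signal, i.e. at single-trial noise level, so it is scaled by
#' `1/sqrt(n_averaged)` to represent the baseline of the epoch average the
#' peak is read from.
#'
#' @param wf An `averaged_waveform` with stored baseline statistics.
#' @return A single number.
#' @export
snr <- function(wf) {
  stopifnot(inherits(wf, "averaged_waveform"))
  if (is.na(wf$baseline_sd) || wf$baseline_sd == 0)
    stop("baseline SD is zero; SNR undefined")
  max(abs(wf$values * wf$norm_factor)) /
    (wf$baseline_sd / sqrt(wf$n_averaged))
}

#' Epoch-average the fNIRS total-hemoglobin trace on the EEG click timeline
#'
#' Computes Delta-HbT = Delta-HbO + Delta-HbR per channel, resamples it
#' (linear interpolation) onto the millisecond epoch grid, cuts one epoch per
#' click and averages per intensity block, exactly mirroring the EEG epoch
#' timeline so the two modalities can be compared sample by sample. Baseline
#' correction uses the first `baseline_s` seconds (default 2 s) preceding
#' each intensity block.
#'
#' @param chromo_rec A `time_series_recording` with modality
#'   `"fnirs_chromophore"` carrying HbO and HbR channels and click events.
#' @param epoch_ms Epoch length, ms (default 12).
#' @param baseline_s Pre-block baseline, seconds (default 2).
#' @param target_rate Epoch grid rate, Hz (default 16000).
#' @return List of `averaged_waveform` objects (one per site x intensity).
#' @export
fnirs_click_trace <- function(chromo_rec, epoch_ms = 12, baseline_s = 2,
                              target_rate = 16000) {
  stopifnot(inherits(chromo_rec, "time_series_recording"))
  hbo <- chromophore(chromo_rec, "HbO")
  hbr <- chromophore(chromo_rec, "HbR")
  hbt <- total_hemoglobin(hbo, hbr)
  fs <- chromo_rec$sample_rate
  t_orig <- (seq_len(ncol(hbt)) - 1L) / fs
  ev <- chromo_rec$events[chromo_rec$events$kind != "silence", , drop = FALSE]
  if (!nrow(ev)) stop("recording carries no stimulus events")
  blocks <- intensity_blocks(chromo_rec$events)
  nsamp <- round(epoch_ms / 1000 * target_rate)
  rel_t <- (seq_len(nsamp) - 1L) / target_rate
  out <- list()
  for (b in seq_len(nrow(blocks))) {
    int <- blocks$intensity[b]
    onsets <- ev$onset[ev$intensity == int]
    onsets <- onsets[onsets + epoch_ms / 1000 <= max(t_orig)]
    xout <- as.vector(outer(rel_t, onsets, `+`))
    for (ch in seq_len(nrow(hbt))) {
      y <- stats::approx(t_orig, hbt[ch, ], xout = xout, rule = 2)$y
      avg <- rowMeans(matrix(y, nrow = nsamp))
      b_lo <- blocks$first_onset[b] - baseline_s
      base <- hbt[ch, t_orig >= b_lo & t_orig < blocks$first_onset[b]]
      bmean <- if (length(base)) mean(base) else 0
      bsd <- if (length(base) > 1L) stats::sd(base) else 0
      avg <- avg - bmean
      nf <- max(abs(avg))
      normalized <- nf > 0
      if (!normalized) nf <- 1
      out[[length(out) + 1L]] <- new_averaged_waveform(
        avg / nf, time_ms = rel_t * 1000,
        channel = rownames(hbt)[ch], intensity = int,
        n_averaged = length(onsets), baseline_mean = bmean,
        baseline_sd = bsd, norm_factor = nf, normalized = normalized,
        sample_rate = target_rate)
    }
  }
  out
}

#' Cross-modal correlation between EEG and fNIRS waveforms
#'
#' Both waveforms are resampled (linear interpolation) onto a common grid -
#' 256 Hz by default, giving lag steps of 1000/256 = 3.90625 ms - and the
#' normalized cross-correlation is evaluated at every lag within the window.
#' The lag with the largest absolute correlation wins (ties: smaller
#' absolute lag, then positive). A positive lag means the second waveform is
#' delayed relative to the first.
#'
#' @param wf1,wf2 `averaged_waveform` objects on overlapping time ranges.
#' @param max_lag_ms Lag window half-width, ms (default 10).
#' @param grid_rate Common resampling rate, Hz (default 256).
#' @return List with elements `r` (signed peak correlation) and `lag_ms`.
#' @export
crossmodal_correlation <- function(wf1, wf2, max_lag_ms = 10,
                                   grid_rate = 256) {
  stopifnot(inherits(wf1, "averaged_waveform"),
            inherits(wf2, "averaged_waveform"))
  step <- 1000 / grid_rate
  t0 <- max(min(wf1$time_ms), min(wf2$time_ms))
  t1 <- min(max(wf1$time_ms), max(wf2$time_ms))
  if (t1 - t0 < 2 * step)
    stop("waveforms do not overlap on the common grid")
  grid <- seq(t0, t1, by = step)
  a <- stats::approx(wf1$time_ms, wf1$values, xout = grid)$y
  b <- stats::approx(wf2$time_ms, wf2$values, xout = grid)$y
  n <- length(grid)
  max_k <- floor(max_lag_ms / step)
  res <- data.frame(k = integer(0), r = numeric(0))
  for (k in -max_k:max_k) {
    i <- seq(max(1L, 1L - k), min(n, n - k))
    if (length(i) < 3L) next
    x <- a[i]; y <- b[i + k]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    res <- rbind(res, data.frame(k = k, r = stats::cor(x, y)))
  }
  if (!nrow(res)) stop("no lag with enough overlap to correlate")
  best <- res[order(-abs(res$r), abs(res$k), -sign(res$k)), ][1, ]
  list(r = best$r, lag_ms = best$k * step)
}
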