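#' Headphone calibration reference point
#'
#' A single acoustic calibration measurement pairing a known sound level with
#' the drive voltage that produced it. All level-to-voltage conversions are
#' made relative to such a point using the standard 20*log10 voltage-ratio
#' relation for sound pressure.
#'
#' @param reference_db Sound level of the reference measurement, dB SPL.
#' @param reference_voltage_mv Drive voltage that produced it, millivolts.
#'   Must be positive.
#' @return An object of class `calibration_point`.
#' @examples
#' calibration_point(100, 370)
#' @export
calibration_point <- function(reference_db, reference_voltage_mv) {
  stopifnot(is.numeric(reference_db), length(reference_db) == 1L,
            is.finite(reference_db),
            is.numeric(reference_voltage_mv), length(reference_voltage_mv) == 1L,
            is.finite(reference_voltage_mv))
  if (reference_voltage_mv <= 0)
    stop("reference_voltage_mv must be positive")
  structure(list(reference_db = reference_db,
                 reference_voltage_mv = reference_voltage_mv),
            class = "calibration_point")
}

#' Convert a target sound level to a drive voltage
#'
#' Inverts the level difference relation
#' \deqn{dB_1 - dB_2 = 20 \log_{10}(V_1 / V_2)}
#' where (dB1, V1) is the calibration reference, giving
#' \eqn{V_2 = V_1 \cdot 10^{(dB_2 - dB_1)/20}}.
#'
#' @param target_db Target stimulus level, dB SPL. Vectorised.
#' @param calib A [calibration_point()].
#' @return Drive voltage(s) in millivolts.
#' @examples
#' db_to_voltage(90, calibration_point(100, 370))  # 117.0 mV
#' @export
db_to_voltage <- function(target_db, calib) {
  stopifnot(inherits(calib, "calibration_point"))
  if (!is.numeric(target_db) || any(!is.finite(target_db)))
    stop("target_db must be finite numeric")
  calib$reference_voltage_mv * 10^((target_db - calib$reference_db) / 20)
}

#' Convert a drive voltage back to a sound level
#'
#' Inverse of [db_to_voltage()]; together they round-trip exactly (up to
#' floating point).
#'
#' @param voltage_mv Drive voltage(s), millivolts, positive.
#' @param calib A [calibration_point()].
#' @return Sound level(s) in dB SPL.
#' @export
voltage_to_db <- function(voltage_mv, calib) {
  stopifnot(inherits(calib, "calibration_point"))
  if (!is.numeric(voltage_mv) || any(!is.finite(voltage_mv)) || any(voltage_mv <= 0))
    stop("voltage_mv must be finite and positive")
  calib$reference_db + 20 * log10(voltage_mv / calib$reference_voltage_mv)
}

new_protocol <- function(events, total_duration, repetition_rate = NA_real_) {
  stopifnot(is.data.frame(events),
            all(c("onset", "duration", "intensity", "kind") %in% names(events)))
  if (nrow(events) > 1L && is.unsorted(events$onset))
    events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events,
                 total_duration = total_duration,
                 repetition_rate = repetition_rate),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  n_stim <- sum(x$events$kind != "silence")
  cat(sprintf("<stimulus_protocol> %d events (%d stimuli), %.3f s total",
              nrow(x$events), n_stim, x$total_duration))
  if (is.finite(x$repetition_rate))
    cat(sprintf(", repetition rate %.4g Hz", x$repetition_rate))
  cat("\n")
  invisible(x)
}

#' Build a click-train stimulation protocol
#'
#' One contiguous block of clicks per stimulus intensity, blocks concatenated
#' in the given order with a configurable inter-block pause (default none).
#' Clicks within a block are spaced at the fixed repetition rate, so the
#' inter-onset interval is `1/rate` seconds.
#'
#' @param rate Click repetition rate, Hz (default 81.9).
#' @param clicks_per_intensity Number of clicks per intensity block
#'   (default 1000).
#' @param intensities Stimulus levels, dB SPL, one block each
#'   (default `c(50, 70, 90)`).
#' @param click_duration Duration of each rectangular click, seconds
#'   (default 1e-4, i.e. 0.1 ms).
#' @param inter_block_gap Silent gap inserted between intensity blocks,
#'   seconds (default 0).
#' @return A `stimulus_protocol` whose events are all of kind `"click"`.
#' @examples
#' p <- build_click_protocol()
#' nrow(p$events)  # 3000
#' @export
build_click_protocol <- function(rate = 81.9,
                                 clicks_per_intensity = 1000L,
                                 intensities = c(50, 70, 90),
                                 click_duration = 1e-4,
                                 inter_block_gap = 0) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("rate must be a positive number")
  stopifnot(clicks_per_intensity >= 0, click_duration > 0, inter_block_gap >= 0)
  clicks_per_intensity <- as.integer(clicks_per_intensity)
  n_blocks <- length(intensities)
  if (clicks_per_intensity == 0L || n_blocks == 0L) {
    ev <- data.frame(onset = numeric(0), duration = numeric(0),
                     intensity = numeric(0), kind = character(0))
    return(new_protocol(ev, total_duration = 0, repetition_rate = rate))
  }
  isi <- 1 / rate
  block_len <- clicks_per_intensity * isi
  onsets <- unlist(lapply(seq_len(n_blocks) - 1L, function(b) {
    b * (block_len + inter_block_gap) + (seq_len(clicks_per_intensity) - 1L) * isi
  }))
  ev <- data.frame(onset = onsets,
                   duration = click_duration,
                   intensity = rep(intensities, each = clicks_per_intensity),
                   kind = "click")
  total <- n_blocks * block_len + (n_blocks - 1L) * inter_block_gap
  new_protocol(ev, total_duration = total, repetition_rate = rate)
}

#' Build the block-design warble stimulation protocol
#'
#' The fixed 92-s sequence used for block-design cortical measurements:
#' 30 s silence, 2 s warble at 50 dB SPL, 13 s silence, 2 s warble at
#' 70 dB SPL, 13 s silence, 2 s warble at 90 dB SPL, 30 s silence. Warble
#' onsets therefore fall at 30, 45 and 60 s.
#'
#' @return A `stimulus_protocol` with three `"warble"` events interleaved
#'   with `"silence"` segments, total duration 92 s.
#' @examples
#' p <- build_warble_protocol()
#' p$total_duration  # 92
#' @export
build_warble_protocol <- function() {
  seg_dur  <- c(30, 2, 13, 2, 13, 2, 30)
  seg_kind <- c("silence", "warble", "silence", "warble", "silence",
                "warble", "silence")
  seg_int  <- c(NA, 50, NA, 70, NA, 90, NA)
  onset <- cumsum(c(0, seg_dur[-length(seg_dur)]))
  ev <- data.frame(onset = onset, duration = seg_dur,
                   intensity = seg_int, kind = seg_kind)
  new_protocol(ev, total_duration = sum(seg_dur))
}

#' Synthesize warble audio samples
#'
#' The warble stimulus is a rapid train of alternating-polarity pulses that
#' drives the headphone diaphragm symmetrically in both directions, so the
#' waveform is zero-mean by construction.
#'
#' @param duration Stimulus duration, seconds (> 0).
#' @param sample_rate Audio sample rate, Hz.
#' @param pulse_rate Internal pulse rate, pulses per second (default 100).
#' @param amplitude Peak amplitude of each pulse (default 1).
#' @return Numeric vector of `round(duration * sample_rate)` samples.
#' @export
synth_warble_samples <- function(duration, sample_rate, pulse_rate = 100,
                                 amplitude = 1) {
  stopifnot(duration > 0, pulse_rate > 0)
  if (sample_rate < 2 * pulse_rate)
    stop("sample_rate too low to represent the pulse train (need >= 2 * pulse_rate)")
  n <- round(duration * sample_rate)
  x <- numeric(n)
  n_pulses <- round(pulse_rate * duration)
  k <- seq_len(n_pulses) - 1L
  idx <- floor(k / pulse_rate * sample_rate) + 1L
  idx <- pmin(idx, n)
  x[idx] <- amplitude * (-1)^k
  x
}

#' Write a stimulation protocol to a tab-separated events file
#'
#' Columns are `onset_s`, `duration_s`, `intensity_db`, `kind` with a header
#' row; onsets are seconds from recording start.
#'
#' @param protocol A `stimulus_protocol`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  ev <- protocol$events
  out <- data.frame(onset_s = ev$onset, duration_s = ev$duration,
                    intensity_db = ev$intensity, kind = ev$kind)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulation protocol from a tab-separated events file
#'
#' @param path Path to a TSV written by [write_protocol()] (header row with
#'   `onset_s`, `duration_s`, `intensity_db`, `kind`).
#' @param repetition_rate Optional repetition rate to record on the protocol.
#' @return A `stimulus_protocol`.
#' @export
read_protocol <- function(path, repetition_rate = NA_real_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "intensity_db", "kind")
  if (!all(need %in% names(tab)))
    stop("protocol file must have columns: ", paste(need, collapse = ", "))
  ev <- data.frame(onset = tab$onset_s, duration = tab$duration_s,
                   intensity = tab$intensity_db, kind = tab$kind)
  last <- if (nrow(ev)) max(ev$onset + ev$duration) else 0
  new_protocol(ev, total_duration = last, repetition_rate = repetition_rate)
}

#' Extract stimulus (non-silence) events from a protocol or recording
#'
#' @param x A `stimulus_protocol` or `time_series_recording`.
#' @return Event data frame with silence rows removed.
#' @keywords internal
stimulus_events <- function(x) {
  ev <- if (inherits(x, "stimulus_protocol")) x$events else x$events
  ev[ev$kind != "silence", , drop = FALSE]
}
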