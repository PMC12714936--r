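#' Construct a multichannel time-series recording
#'
#' The common container for EEG voltages, raw fNIRS optical intensities and
#' fNIRS chromophore concentration changes. Data are stored as a channels x
#' samples matrix with a uniform sample rate; stimulus events are carried
#' alongside as a data frame of onsets (seconds from recording start,
#' 0-based, half-open durations).
#'
#' @param data Numeric matrix, channels x samples.
#' @param sample_rate Sampling rate, Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param events Data frame with columns `onset`, `duration`, `intensity`,
#'   `kind`, or a `stimulus_protocol` (its events are copied), or `NULL`.
#' @param modality One of `"eeg"`, `"fnirs_raw"`, `"fnirs_chromophore"`.
#' @return An object of class `time_series_recording`.
#' @export
time_series_recording <- function(data, sample_rate, channel_labels,
                                  events = NULL,
                                  modality = c("eeg", "fnirs_raw",
                                               "fnirs_chromophore")) {
  modality <- match.arg(modality)
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.numeric(data), sample_rate > 0,
            length(channel_labels) == nrow(data))
  if (inherits(events, "stimulus_protocol")) events <- events$events
  if (is.null(events))
    events <- data.frame(onset = numeric(0), duration = numeric(0),
                         intensity = numeric(0), kind = character(0))
  span <- ncol(data) / sample_rate
  if (nrow(events) && any(events$onset < 0 | events$onset > span))
    stop("events must lie within the recording span")
  structure(list(data = data,
                 sample_rate = sample_rate,
                 channel_labels = as.character(channel_labels),
                 events = events,
                 modality = modality),
            class = "time_series_recording")
}

#' @export
print.time_series_recording <- function(x, ...) {
  cat(sprintf("<time_series_recording> %s: %d channel(s) x %d samples @ %g Hz (%.2f s), %d event(s)\n",
              x$modality, nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate, nrow(x$events)))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec A `time_series_recording`.
#' @return Integer sample count.
#' @keywords internal
n_samples <- function(rec) ncol(rec$data)

#' Extract one chromophore from a chromophore recording
#'
#' Chromophore recordings label channels as `"<site> <chromophore>"`
#' (e.g. `"S1-D1 HbO"`). This returns the sub-matrix for one chromophore
#' with plain site labels.
#'
#' @param rec A `time_series_recording` with modality `"fnirs_chromophore"`.
#' @param which `"HbO"`, `"HbR"` or `"HbT"`.
#' @return Matrix sites x samples with rownames set to the site labels.
#' @export
chromophore <- function(rec, which = c("HbO", "HbR", "HbT")) {
  which <- match.arg(which)
  stopifnot(inherits(rec, "time_series_recording"),
            rec$modality == "fnirs_chromophore")
  sel <- grepl(paste0(" ", which, "$"), rec$channel_labels)
  if (!any(sel)) stop("recording carries no ", which, " channels")
  m <- rec$data[sel, , drop = FALSE]
  rownames(m) <- sub(paste0(" ", which, "$"), "", rec$channel_labels[sel])
  m
}
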