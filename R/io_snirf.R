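# SNIRF (Shared Near Infrared Spectroscopy Format) reader/writer on HDF5.
# Raw optical intensity uses dataType 1 (CW amplitude); chromophore
# concentration changes use dataType 99999 (processed) with dataTypeLabel
# "HbO" / "HbR" / "HbT". Channel labels are source-detector pairs ("S1-D2").

parse_site <- function(label) {
  m <- regmatches(label, regexec("^S([0-9]+)-D([0-9]+)", label))[[1]]
  if (length(m) != 3L)
    stop("channel label not of the form 'S<i>-D<j>': ", label)
  c(src = as.integer(m[2]), det = as.integer(m[3]))
}

#' Write an fNIRS recording to a SNIRF file
#'
#' Raw-intensity recordings are stored as continuous-wave amplitude
#' measurements; chromophore recordings as processed concentration channels
#' with `dataTypeLabel` HbO/HbR/HbT. Stimulus events become `stim` groups
#' (one per event kind) with onset/duration/intensity rows.
#'
#' @param rec A `time_series_recording` with modality `"fnirs_raw"` or
#'   `"fnirs_chromophore"`.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_fnirs <- function(rec, path) {
  stopifnot(inherits(rec, "time_series_recording"),
            rec$modality %in% c("fnirs_raw", "fnirs_chromophore"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write("1.1", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/metaDataTags")
  meta <- c(SubjectID = "synthetic", MeasurementDate = "2000-01-01",
            MeasurementTime = "00:00:00", LengthUnit = "mm",
            TimeUnit = "s", FrequencyUnit = "Hz")
  for (k in names(meta)) rhdf5::h5write(meta[[k]], path,
                                        paste0("nirs/metaDataTags/", k))
  rhdf5::h5createGroup(path, "nirs/data1")
  n <- ncol(rec$data)
  rhdf5::h5write(t(rec$data), path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((seq_len(n) - 1) / rec$sample_rate, path, "nirs/data1/time")

  if (rec$modality == "fnirs_raw") {
    sites <- rec$channel_labels
    labels <- rep(NA_character_, length(sites))
  } else {
    sites <- sub(" (HbO|HbR|HbT)$", "", rec$channel_labels)
    labels <- sub("^.* ", "", rec$channel_labels)
    if (!all(labels %in% c("HbO", "HbR", "HbT")))
      stop("chromophore channel labels must end in HbO, HbR or HbT")
  }
  sd <- t(vapply(sites, parse_site, c(src = 0L, det = 0L)))
  for (i in seq_along(sites)) {
    g <- sprintf("nirs/data1/measurementList%d", i)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(sd[i, "src"], path, paste0(g, "/sourceIndex"))
    rhdf5::h5write(sd[i, "det"], path, paste0(g, "/detectorIndex"))
    rhdf5::h5write(1L, path, paste0(g, "/wavelengthIndex"))
    rhdf5::h5write(1L, path, paste0(g, "/dataTypeIndex"))
    if (rec$modality == "fnirs_raw") {
      rhdf5::h5write(1L, path, paste0(g, "/dataType"))
    } else {
      rhdf5::h5write(99999L, path, paste0(g, "/dataType"))
      rhdf5::h5write(labels[i], path, paste0(g, "/dataTypeLabel"))
    }
  }

  n_src <- max(sd[, "src"]); n_det <- max(sd[, "det"])
  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(c(760, 850), path, "nirs/probe/wavelengths")
  rhdf5::h5write(cbind(10 * seq_len(n_src), rep(0, n_src)), path,
                 "nirs/probe/sourcePos2D")
  rhdf5::h5write(cbind(10 * seq_len(n_det) + 5, rep(30, n_det)), path,
                 "nirs/probe/detectorPos2D")

  kinds <- unique(rec$events$kind)
  for (k in seq_along(kinds)) {
    g <- sprintf("nirs/stim%d", k)
    sel <- rec$events$kind == kinds[k]
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(kinds[k], path, paste0(g, "/name"))
    rhdf5::h5write(cbind(rec$events$onset[sel], rec$events$duration[sel],
                         rec$events$intensity[sel]),
                   path, paste0(g, "/data"))
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read an fNIRS recording from a SNIRF file
#'
#' The modality is set from the measurement-list data-type code: 1
#' (continuous-wave amplitude) gives `"fnirs_raw"`; 99999 (processed) with
#' HbO/HbR/HbT labels gives `"fnirs_chromophore"`. Any other code is an
#' error naming the code. A concentration file carrying HbO without HbR
#' (or vice versa) is rejected.
#'
#' @param path Path to a SNIRF file.
#' @return A `time_series_recording`.
#' @export
read_fnirs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  dat <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  time <- as.numeric(rhdf5::h5read(path, "nirs/data1/time"))
  if (length(time) < 2L) stop("SNIRF time vector too short")
  sample_rate <- 1 / stats::median(diff(time))

  ml_names <- ls$name[grepl("^measurementList[0-9]+$", ls$name)]
  ml_idx <- sort(as.integer(sub("measurementList", "", ml_names)))
  n_ch <- length(ml_idx)
  if (n_ch == 0L) stop("SNIRF file has no measurement list")
  if (ncol(dat) != n_ch) stop("dataTimeSeries width does not match measurement list")

  labels <- character(n_ch)
  dtypes <- integer(n_ch)
  dlabels <- character(n_ch)
  for (i in seq_len(n_ch)) {
    g <- sprintf("nirs/data1/measurementList%d", ml_idx[i])
    src <- as.integer(rhdf5::h5read(path, paste0(g, "/sourceIndex")))
    det <- as.integer(rhdf5::h5read(path, paste0(g, "/detectorIndex")))
    dtypes[i] <- as.integer(rhdf5::h5read(path, paste0(g, "/dataType")))
    site <- sprintf("S%d-D%d", src, det)
    if (dtypes[i] == 1L) {
      labels[i] <- site
    } else if (dtypes[i] == 99999L) {
      dlabels[i] <- as.character(rhdf5::h5read(path, paste0(g, "/dataTypeLabel")))
      labels[i] <- paste(site, dlabels[i])
    } else {
      stop("unsupported SNIRF dataType code: ", dtypes[i])
    }
  }
  if (length(unique(dtypes)) != 1L)
    stop("mixed raw and processed measurement lists are not supported")
  modality <- if (dtypes[1] == 1L) "fnirs_raw" else "fnirs_chromophore"
  if (modality == "fnirs_chromophore") {
    has <- unique(dlabels)
    if (xor("HbO" %in% has, "HbR" %in% has))
      stop("concentration file must carry both HbO and HbR channels")
  }

  stim_names <- unique(ls$name[grepl("^stim[0-9]+$", ls$name)])
  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       intensity = numeric(0), kind = character(0))
  for (s in stim_names) {
    kind <- as.character(rhdf5::h5read(path, paste0("nirs/", s, "/name")))
    d <- rhdf5::h5read(path, paste0("nirs/", s, "/data"))
    d <- matrix(as.numeric(d), ncol = 3)
    events <- rbind(events,
                    data.frame(onset = d[, 1], duration = d[, 2],
                               intensity = ifelse(is.nan(d[, 3]), NA, d[, 3]),
                               kind = kind))
  }
  events <- events[order(events$onset), , drop = FALSE]
  rownames(events) <- NULL
  time_series_recording(t(dat), sample_rate, labels, events = events,
                        modality = modality)
}
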