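# European Data Format (EDF+C) reader/writer.
#
# EDF stores 16-bit integers with per-signal physical/digital scaling, so a
# round-trip is exact only to the format's quantization step (about
# range/65535). Events are carried in an "EDF Annotations" signal as
# time-stamped annotation lists (TALs). Header fields are fixed-width ASCII.

fmt_ascii <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("header field too long: ", s)
  formatC(s, width = width, flag = "-")
}

# number that fits an 8-char EDF header field, reparsable
fmt_num8 <- function(x) {
  for (d in 8:1) {
    s <- formatC(signif(x, d), format = "g", digits = d)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot format ", x, " in 8 characters")
}

TAB_SEP <- "\x15"  # onset/duration separator inside a TAL
ANN_SEP <- "\x14"  # annotation separator

encode_tals <- function(events) {
  # TALs are NUL-terminated, and R strings cannot hold NUL, so build raw
  nul <- as.raw(0)
  tals <- c(charToRaw("+0\x14\x14"), nul)  # timekeeping TAL, single record
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      label <- paste(events$kind[i],
                     ifelse(is.na(events$intensity[i]), "NA",
                            format(events$intensity[i])))
      tals <- c(tals,
                charToRaw(sprintf("+%.9g%s%.9g%s%s%s",
                                  events$onset[i], TAB_SEP,
                                  events$duration[i], ANN_SEP, label,
                                  ANN_SEP)),
                nul)
    }
  }
  tals
}

decode_tals <- function(bytes) {
  # split the raw stream at NUL terminators, then decode each TAL
  grp <- cumsum(c(FALSE, (bytes == as.raw(0))[-length(bytes)]))
  chunks <- vapply(split(bytes, grp), function(p) {
    p <- p[p != as.raw(0)]
    if (length(p)) rawToChar(p) else ""
  }, "", USE.NAMES = FALSE)
  ev <- list()
  for (ch in chunks) {
    if (!nzchar(ch)) next
    parts <- strsplit(ch, ANN_SEP, fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(parts[2])) next  # timekeeping TAL
    od <- strsplit(parts[1], TAB_SEP, fixed = TRUE)[[1]]
    onset <- as.numeric(od[1])
    duration <- if (length(od) > 1L) as.numeric(od[2]) else 0
    lab <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    kind <- lab[1]
    intensity <- if (length(lab) > 1L) suppressWarnings(as.numeric(lab[2])) else NA_real_
    ev[[length(ev) + 1L]] <- data.frame(onset = onset, duration = duration,
                                        intensity = intensity, kind = kind)
  }
  if (length(ev)) do.call(rbind, ev)
  else data.frame(onset = numeric(0), duration = numeric(0),
                  intensity = numeric(0), kind = character(0))
}

#' Write an EEG recording to a European Data Format (EDF+C) file
#'
#' One data record holds the whole recording; stimulus events are encoded as
#' EDF+ annotations. Samples are quantized to the format's 16-bit integers
#' with per-channel scaling to the data range, so values round-trip to the
#' quantization step (about 1/65000 of the channel range), not exactly.
#'
#' @param rec A `time_series_recording` with modality `"eeg"` (units uV).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(rec, path) {
  stopifnot(inherits(rec, "time_series_recording"))
  n_ch <- nrow(rec$data)
  n <- ncol(rec$data)
  if (n_ch == 0L || n == 0L) stop("recording has no data")

  ann_bytes <- encode_tals(rec$events)
  if (length(ann_bytes) %% 2L) ann_bytes <- c(ann_bytes, as.raw(0))
  ann_spr <- length(ann_bytes) / 2L

  ns <- n_ch + 1L  # + annotation signal
  pmin <- pmax <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    lo <- min(rec$data[ch, ]); hi <- max(rec$data[ch, ])
    if (hi <= lo) hi <- lo + 1
    # use the 8-char header representation for quantization so that writer
    # and reader agree on the scaling exactly
    pmin[ch] <- as.numeric(fmt_num8(lo))
    pmax[ch] <- as.numeric(fmt_num8(hi))
    if (pmax[ch] <= pmin[ch]) pmax[ch] <- pmin[ch] + 1
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(fmt_ascii("0", 8))
  wr(fmt_ascii("X X X X", 80))
  wr(fmt_ascii("Startdate X X X X", 80))
  wr(fmt_ascii("01.01.00", 8))
  wr(fmt_ascii("00.00.00", 8))
  wr(fmt_ascii(256L * (ns + 1L), 8))
  wr(fmt_ascii(paste0("EDF+C fs=", format(rec$sample_rate, digits = 12)), 44))
  wr(fmt_ascii(1L, 8))                       # one data record
  wr(fmt_ascii(fmt_num8(n / rec$sample_rate), 8))
  wr(fmt_ascii(ns, 4))

  labels <- c(substr(rec$channel_labels, 1L, 16L), "EDF Annotations")
  for (l in labels) wr(fmt_ascii(l, 16))
  for (i in seq_len(ns)) wr(fmt_ascii("", 80))            # transducer
  for (i in seq_len(ns)) wr(fmt_ascii(if (i <= n_ch) "uV" else "", 8))
  for (i in seq_len(ns)) wr(fmt_ascii(if (i <= n_ch) fmt_num8(pmin[i]) else "-1", 8))
  for (i in seq_len(ns)) wr(fmt_ascii(if (i <= n_ch) fmt_num8(pmax[i]) else "1", 8))
  for (i in seq_len(ns)) wr(fmt_ascii("-32768", 8))
  for (i in seq_len(ns)) wr(fmt_ascii("32767", 8))
  for (i in seq_len(ns)) wr(fmt_ascii("", 80))            # prefiltering
  for (i in seq_len(ns)) wr(fmt_ascii(if (i <= n_ch) n else ann_spr, 8))
  for (i in seq_len(ns)) wr(fmt_ascii("", 32))

  for (ch in seq_len(n_ch)) {
    d <- round((rec$data[ch, ] - pmin[ch]) / (pmax[ch] - pmin[ch]) * 65535 - 32768)
    d <- pmin(pmax(d, -32768), 32767)
    writeBin(as.integer(d), con, size = 2L, endian = "little")
  }
  writeBin(ann_bytes, con)
  invisible(path)
}

#' Read an EEG recording from a European Data Format file
#'
#' Reconstructs the channel data (physical units), the sample rate and the
#' stimulus events from the EDF+ annotation signal. A file without an
#' annotation signal yields a recording with an empty event table and a
#' warning.
#'
#' @param path Path to an EDF file.
#' @return A `time_series_recording` with modality `"eeg"`.
#' @export
read_eeg <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar) {
    s <- readChar(con, nchar, useBytes = TRUE)
    if (nchar(s, type = "bytes") < nchar) stop("malformed EDF file: truncated header")
    trimws(s)
  }
  version <- rd(8)
  if (version != "0") stop("malformed EDF file: bad version field")
  rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("EDF file declares no signals")

  labels <- trimws(vapply(seq_len(ns), function(i) readChar(con, 16, useBytes = TRUE), ""))
  for (i in seq_len(ns)) readChar(con, 80, useBytes = TRUE)
  dims <- trimws(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), ""))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), ""))
  for (i in seq_len(ns)) readChar(con, 80, useBytes = TRUE)
  spr <- as.integer(vapply(seq_len(ns), function(i) readChar(con, 8, useBytes = TRUE), ""))
  for (i in seq_len(ns)) readChar(con, 32, useBytes = TRUE)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  if (length(sig_idx) == 0L) stop("EDF file contains no data signals")
  if (length(unique(spr[sig_idx])) != 1L)
    stop("signals with differing samples per record are not supported")

  raw_sig <- vector("list", ns)
  for (i in seq_len(ns)) raw_sig[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        raw_sig[[i]][[r]] <- readBin(con, "raw", n = 2L * spr[i])
      } else {
        raw_sig[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2L,
                                     endian = "little")
        if (length(raw_sig[[i]][[r]]) < spr[i])
          stop("malformed EDF file: truncated data record")
      }
    }
  }

  n <- spr[sig_idx[1]] * n_rec
  data <- matrix(0, nrow = length(sig_idx), ncol = n)
  for (k in seq_along(sig_idx)) {
    i <- sig_idx[k]
    d <- unlist(raw_sig[[i]])
    data[k, ] <- pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
  }

  fs_match <- regmatches(reserved, regexpr("fs=[0-9.eE+-]+", reserved))
  sample_rate <- if (length(fs_match)) as.numeric(sub("fs=", "", fs_match))
                 else spr[sig_idx[1]] / rec_dur

  if (any(is_ann)) {
    events <- decode_tals(do.call(c, raw_sig[[which(is_ann)[1]]]))
  } else {
    warning("EDF file has no annotation signal; returning empty event table")
    events <- NULL
  }
  time_series_recording(data, sample_rate, labels[sig_idx],
                        events = events, modality = "eeg")
}
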