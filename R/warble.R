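# Block-design fNIRS battery: chromophore arithmetic, smoothing, percent
# change epoching, grand average, PCA, task GLM with FDR, time-locked
# cross-correlation, stimulation-vs-silence contrasts and the spatial
# repeated-measures ANOVA with Holm post-hocs.

#' Total hemoglobin change from oxy- and deoxyhemoglobin
#'
#' Elementwise \eqn{\Delta[HbT] = \Delta[HbO] + \Delta[HbR]}.
#'
#' @param hbo,hbr Numeric vectors or matrices of equal shape.
#' @return Their elementwise sum.
#' @export
total_hemoglobin <- function(hbo, hbr) {
  if (!identical(dim(hbo), dim(hbr)) || length(hbo) != length(hbr))
    stop("hbo and hbr must have identical shapes")
  hbo + hbr
}

# centered moving average with edge truncation; w in samples
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-average smoothing of a recording or matrix
#'
#' Centered moving average whose window is given in milliseconds (default
#' 200 ms); at the edges the window is truncated so the output has the same
#' length as the input. Suppresses high-frequency noise while preserving the
#' slow hemodynamic shape.
#'
#' @param x A `time_series_recording`, matrix (channels x samples) or vector.
#' @param window_ms Window length, ms (default 200).
#' @param sample_rate Required when `x` is not a recording.
#' @return Same type as `x`, smoothed.
#' @export
smooth_series <- function(x, window_ms = 200, sample_rate = NULL) {
  if (inherits(x, "time_series_recording")) {
    w <- max(1L, round(window_ms / 1000 * x$sample_rate))
    out <- x
    for (ch in seq_len(nrow(x$data)))
      out$data[ch, ] <- moving_average(x$data[ch, ], w)
    return(out)
  }
  if (is.null(sample_rate)) stop("sample_rate required for matrix/vector input")
  w <- max(1L, round(window_ms / 1000 * sample_rate))
  if (w < 1L) stop("window must span at least one sample")
  if (is.matrix(x)) t(apply(x, 1L, moving_average, w = w))
  else moving_average(x, w)
}

#' Epoch a recording around block onsets as percent change from baseline
#'
#' For each stimulus onset, cuts a window (default -5 to +15 s) and expresses
#' it as `100 * (x - baseline_mean) / |baseline_mean|`, where the baseline
#' mean is taken over the pre-stimulus part of the window (default -5 to
#' 0 s) of the raw intensity trace. Epochs whose window escapes the
#' recording are dropped and counted.
#'
#' @param rec A `time_series_recording` (raw intensity) or channels x samples
#'   matrix.
#' @param onsets Stimulus onsets in seconds; defaults to the recording's
#'   non-silence events.
#' @param window `c(start, end)` of the epoch relative to onset, seconds.
#' @param baseline `c(start, end)` of the baseline, seconds relative to
#'   onset.
#' @param sample_rate Required when `rec` is a matrix.
#' @return An object of class `block_epochs`: list with `epochs` (one row
#'   per channel x onset, columns = time), `time_s`, `index` (data frame
#'   channel/onset), and `n_dropped`.
#' @export
epoch_blocks <- function(rec, onsets = NULL, window = c(-5, 15),
                         baseline = c(-5, 0), sample_rate = NULL) {
  if (inherits(rec, "time_series_recording")) {
    data <- rec$data
    fs <- rec$sample_rate
    labels <- rec$channel_labels
    if (is.null(onsets))
      onsets <- rec$events$onset[rec$events$kind != "silence"]
  } else {
    data <- if (is.matrix(rec)) rec else matrix(rec, nrow = 1L)
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for matrix input")
    labels <- rownames(data)
    if (is.null(labels)) labels <- sprintf("ch%d", seq_len(nrow(data)))
    if (is.null(onsets)) stop("onsets required for matrix input")
  }
  stopifnot(length(window) == 2L, window[1] < window[2],
            baseline[1] >= window[1], baseline[2] <= window[2])
  n <- ncol(data)
  rel_idx <- round(window[1] * fs):round(window[2] * fs)
  time_s <- rel_idx / fs
  base_sel <- time_s >= baseline[1] & time_s < baseline[2]
  if (!any(base_sel)) stop("baseline window contains no samples")
  rows <- list()
  index <- list()
  n_dropped <- 0L
  for (on in onsets) {
    idx <- round(on * fs) + 1L + rel_idx
    if (idx[1] < 1L || idx[length(idx)] > n) {
      n_dropped <- n_dropped + nrow(data)
      next
    }
    for (ch in seq_len(nrow(data))) {
      x <- data[ch, idx]
      ref <- mean(x[base_sel])
      if (abs(ref) < .Machine$double.eps)
        stop("baseline reference is zero; percent change undefined")
      rows[[length(rows) + 1L]] <- 100 * (x - ref) / abs(ref)
      index[[length(index) + 1L]] <- data.frame(channel = labels[ch],
                                                onset = on)
    }
  }
  structure(list(epochs = if (length(rows)) do.call(rbind, rows)
                          else matrix(0, 0L, length(rel_idx)),
                 time_s = time_s,
                 index = if (length(index)) do.call(rbind, index)
                         else data.frame(channel = character(0),
                                         onset = numeric(0)),
                 n_dropped = n_dropped),
            class = "block_epochs")
}

#' @export
print.block_epochs <- function(x, ...) {
  cat(sprintf("<block_epochs> %d epoch(s) x %d samples, %d dropped\n",
              nrow(x$epochs), ncol(x$epochs), x$n_dropped))
  invisible(x)
}

#' Grand average with standard error band
#'
#' Pointwise mean across epochs and the standard error of the mean
#' (sd / sqrt(n)).
#'
#' @param epochs A `block_epochs` object or an epochs x time matrix.
#' @return List with `mean`, `sem`, `n` and (if available) `time_s`.
#' @export
grand_average <- function(epochs) {
  time_s <- NULL
  if (inherits(epochs, "block_epochs")) {
    time_s <- epochs$time_s
    epochs <- epochs$epochs
  }
  stopifnot(is.matrix(epochs))
  if (nrow(epochs) < 2L) stop("need at least 2 epochs for a grand average")
  m <- colMeans(epochs)
  sem <- apply(epochs, 2L, stats::sd) / sqrt(nrow(epochs))
  list(mean = m, sem = sem, n = nrow(epochs), time_s = time_s)
}

#' Principal component analysis of epoched responses
#'
#' Identifies the dominant recurring temporal patterns across epochs. Time
#' points are mean-centered and the principal axes in epoch space are
#' returned as temporal components, ordered by explained variance.
#'
#' @param epochs A `block_epochs` object or an epochs x time matrix.
#' @param n_components Number of components to keep (default all).
#' @return An object of class `pca_result` with `components` (time x k
#'   matrix), `explained` (variance fractions), `scores` (epochs x k) and
#'   `time_s`.
#' @export
pca_epochs <- function(epochs, n_components = NULL) {
  time_s <- NULL
  if (inherits(epochs, "block_epochs")) {
    time_s <- epochs$time_s
    epochs <- epochs$epochs
  }
  stopifnot(is.matrix(epochs))
  if (nrow(epochs) < 2L) stop("need at least 2 epochs for PCA")
  fit <- stats::prcomp(epochs, center = TRUE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  k <- if (is.null(n_components)) ncol(fit$rotation)
       else min(n_components, ncol(fit$rotation))
  structure(list(components = fit$rotation[, seq_len(k), drop = FALSE],
                 explained = expl[seq_len(k)],
                 scores = fit$x[, seq_len(k), drop = FALSE],
                 time_s = time_s),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d component(s); PC1 explains %.1f%% of variance\n",
              ncol(x$components), 100 * x$explained[1]))
  invisible(x)
}

#' Task regressor for the block-design GLM
#'
#' A boxcar at each warble onset (stimulus duration wide) convolved with a
#' unimodal hemodynamic kernel whose extremum falls `trough_latency` seconds
#' after onset. With `negative = TRUE` (the GLM default) the kernel is
#' negative-going, modeling the task-locked intensity decrease, so the
#' fitted amplitude of a decreasing signal is positive.
#'
#' @param protocol A `stimulus_protocol` (or event data frame).
#' @param sample_rate Hz.
#' @param n_samples Length of the regressor.
#' @param trough_latency Kernel extremum latency, seconds (default 12).
#' @param shape Gamma shape of the kernel (default 4).
#' @param negative Logical: negative-going kernel (default TRUE).
#' @return Numeric vector of length `n_samples`, extremum magnitude 1.
#' @export
task_regressor <- function(protocol, sample_rate, n_samples,
                           trough_latency = 12, shape = 4, negative = TRUE) {
  ev <- if (inherits(protocol, "stimulus_protocol")) stimulus_events(protocol)
        else protocol[protocol$kind != "silence", , drop = FALSE]
  box <- numeric(n_samples)
  for (i in seq_len(nrow(ev))) {
    i0 <- round(ev$onset[i] * sample_rate) + 1L
    i1 <- min(round((ev$onset[i] + ev$duration[i]) * sample_rate), n_samples)
    if (i0 <= n_samples) box[i0:max(i0, i1)] <- 1
  }
  kern_t <- seq(0, 4 * trough_latency, by = 1 / sample_rate)
  kern <- hemo_kernel(kern_t, trough_latency, shape)
  reg <- stats::convolve(box, rev(kern), type = "open")[seq_len(n_samples)]
  if (max(abs(reg)) > 0) reg <- reg / max(abs(reg))
  if (negative) -reg else reg
}

# OLS fit of y on X returning beta/t/p for column `which`
ols_stat <- function(X, y, which) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient design matrix")
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  xtxi <- chol2inv(qr.R(qr_x))
  se <- sqrt(s2 * diag(xtxi))
  t_stat <- beta / se
  list(beta = beta[which], se = se[which], t = t_stat[which],
       p = 2 * stats::pt(-abs(t_stat[which]), df), df = df,
       sigma2 = s2, residuals = as.numeric(res))
}

#' Fit the task GLM to an fNIRS recording
#'
#' Per channel, ordinary least squares of the (fractional) intensity series
#' on a design with intercept, linear drift and the task regressor (2-s
#' boxcars at the warble onsets convolved with a negative-going hemodynamic
#' kernel). Because fNIRS noise carries narrowband systemic oscillations
#' (cardiac, respiratory, vasomotor), the residual-based parametric t-test
#' is miscalibrated; per-channel significance is therefore assessed by a
#' circular-shift permutation test by default: the amplitude estimate is
#' recomputed with the task regressor circularly shifted to `n_perm`
#' deterministic offsets (all at least `min_shift_s` from zero), which
#' preserves the noise autocorrelation and yields a well-calibrated null.
#' The parametric t and its p-value are reported alongside.
#'
#' @param rec A `time_series_recording` (modality `"fnirs_raw"`; data are
#'   divided by each channel's mean so betas are fractional) or a channels x
#'   samples matrix already on a fractional scale.
#' @param protocol A `stimulus_protocol`; defaults to the recording's events.
#' @param trough_latency,shape Hemodynamic kernel parameters (see
#'   [task_regressor()]).
#' @param p_method `"permutation"` (default) or `"parametric"` for the `p`
#'   column.
#' @param n_perm Number of circular shifts (default 199).
#' @param min_shift_s Minimum shift away from the true alignment, seconds
#'   (default 5).
#' @param sample_rate Required for matrix input.
#' @return An object of class `glm_fit`: data frame `channels` with beta,
#'   se, t, p (selected method) and p_param per channel, plus the regressor
#'   used.
#' @export
glm_task <- function(rec, protocol = NULL, trough_latency = 12, shape = 4,
                     p_method = c("permutation", "parametric"),
                     n_perm = 199, min_shift_s = 5,
                     sample_rate = NULL) {
  p_method <- match.arg(p_method)
  if (inherits(rec, "time_series_recording")) {
    fs <- rec$sample_rate
    data <- rec$data
    if (rec$modality == "fnirs_raw") {
      mu <- rowMeans(data)
      if (any(mu == 0)) stop("channel with zero mean intensity")
      data <- data / mu
    }
    labels <- rec$channel_labels
    if (is.null(protocol)) protocol <- rec$events
  } else {
    data <- if (is.matrix(rec)) rec else matrix(rec, nrow = 1L)
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for matrix input")
    labels <- rownames(data)
    if (is.null(labels)) labels <- sprintf("ch%d", seq_len(nrow(data)))
    if (is.null(protocol)) stop("protocol required for matrix input")
  }
  ev <- if (inherits(protocol, "stimulus_protocol")) protocol$events else protocol
  n <- ncol(data)
  reg <- task_regressor(ev, fs, n, trough_latency, shape, negative = TRUE)
  t_sec <- (seq_len(n) - 1L) / fs
  X <- cbind(intercept = 1, drift = t_sec - mean(t_sec), task = reg)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")

  # deterministic circular shifts, all at least min_shift_s from alignment
  perm_beta <- NULL
  if (p_method == "permutation") {
    min_shift <- ceiling(min_shift_s * fs)
    if (2L * min_shift >= n)
      stop("recording too short for the requested minimum shift")
    offsets <- unique(round(seq(min_shift, n - min_shift,
                                length.out = n_perm)))
    # project out intercept + drift once, then each shifted-regressor beta
    # is a ratio of dot products
    Z <- X[, 1:2]
    Pz <- function(v) v - Z %*% qr.coef(qr(Z), v)
    reg_shifts <- vapply(offsets, function(k)
      as.numeric(Pz(reg[((seq_len(n) - 1L + k) %% n) + 1L])), numeric(n))
    ss_shift <- colSums(reg_shifts^2)
  }

  out <- data.frame(channel = labels, beta = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_, p_param = NA_real_)
  for (ch in seq_len(nrow(data))) {
    y <- data[ch, ]
    fit <- ols_stat(X, y, which = 3L)
    out$beta[ch] <- fit$beta
    out$se[ch] <- fit$se
    out$t[ch] <- fit$t
    out$p_param[ch] <- fit$p
    if (p_method == "permutation") {
      yr <- as.numeric(Pz(y))
      b_null <- as.numeric(crossprod(reg_shifts, yr)) / ss_shift
      out$p[ch] <- (1 + sum(abs(b_null) >= abs(fit$beta))) /
        (length(b_null) + 1)
    } else {
      out$p[ch] <- fit$p
    }
  }
  structure(list(channels = out, regressor = reg, sample_rate = fs),
            class = "glm_fit")
}

#' Group-level inference on per-subject GLM amplitudes
#'
#' One-sample t-test across subjects per channel, Benjamini-Hochberg FDR
#' correction across channels, significance at corrected p below alpha.
#'
#' @param betas Subjects x channels matrix of per-subject response
#'   amplitudes.
#' @param alpha Significance level (default 0.05).
#' @param channel_names Optional channel names; default "Ch 1", "Ch 2", ...
#' @return Data frame with channel, t_statistic, p_value, mean_beta,
#'   p_fdr and significant columns.
#' @export
glm_group <- function(betas, alpha = 0.05, channel_names = NULL) {
  betas <- as.matrix(betas)
  if (nrow(betas) < 2L) stop("need at least 2 subjects")
  C <- ncol(betas)
  if (is.null(channel_names)) channel_names <- sprintf("Ch %d", seq_len(C))
  tt <- lapply(seq_len(C), function(j) stats::t.test(betas[, j]))
  p <- vapply(tt, function(x) x$p.value, 0)
  p_fdr <- fdr_correct(p)
  data.frame(channel = channel_names,
             t_statistic = vapply(tt, function(x) unname(x$statistic), 0),
             p_value = p,
             mean_beta = colMeans(betas),
             p_fdr = p_fdr,
             significant = p_fdr < alpha)
}

#' Time-locked cross-correlation of channels with the task regressor
#'
#' For each channel, the Pearson correlation with the task regressor is
#' evaluated at every lag within the window and the lag with the largest
#' absolute correlation is reported, with its sign preserved (so a signal
#' that decreases when the positive-going regressor rises yields a negative
#' peak). The unnormalized cross-covariance at the same lag is also
#' reported.
#'
#' @param series Channels x samples matrix (or vector), e.g. fractional
#'   intensity.
#' @param regressor Task regressor on the same grid.
#' @param sample_rate Hz.
#' @param max_lag_s Lag window half-width, seconds (default 5).
#' @return Data frame with channel, peak_r, lag_s, peak_cov.
#' @export
crosscorr_task <- function(series, regressor, sample_rate, max_lag_s = 5) {
  data <- if (is.matrix(series)) series else matrix(series, nrow = 1L)
  n <- ncol(data)
  if (length(regressor) != n)
    stop("series and regressor must be on the same grid")
  labels <- rownames(data)
  if (is.null(labels)) labels <- sprintf("ch%d", seq_len(nrow(data)))
  max_k <- floor(max_lag_s * sample_rate)
  out <- data.frame(channel = labels, peak_r = NA_real_, lag_s = NA_real_,
                    peak_cov = NA_real_)
  for (ch in seq_len(nrow(data))) {
    x <- data[ch, ]
    best_r <- 0; best_k <- 0L; best_cov <- 0
    found <- FALSE
    for (k in -max_k:max_k) {
      i <- seq(max(1L, 1L - k), min(n, n - k))
      if (length(i) < 3L) next
      a <- x[i]; b <- regressor[i + k]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      r <- stats::cor(a, b)
      if (!found || abs(r) > abs(best_r)) {
        best_r <- r; best_k <- k
        best_cov <- sum((a - mean(a)) * (b - mean(b)))
        found <- TRUE
      }
    }
    if (found) {
      out$peak_r[ch] <- best_r
      out$lag_s[ch] <- best_k / sample_rate
      out$peak_cov[ch] <- best_cov
    }
  }
  out
}

#' Group-level inference on cross-correlation peaks
#'
#' One-sample t-test across subjects on the per-subject peak correlations,
#' per channel, with FDR correction across channels; the mean unnormalized
#' peak cross-covariance is reported alongside.
#'
#' @param peak_r Subjects x channels matrix of peak correlations.
#' @param peak_cov Subjects x channels matrix of peak cross-covariances.
#' @param alpha Significance level (default 0.05).
#' @param channel_names Optional channel names.
#' @return Data frame with channel, t_statistic, p_value, mean_peak_r,
#'   mean_peak_cov, p_fdr and significant columns.
#' @export
crosscorr_group <- function(peak_r, peak_cov = NULL, alpha = 0.05,
                            channel_names = NULL) {
  peak_r <- as.matrix(peak_r)
  if (nrow(peak_r) < 2L) stop("need at least 2 subjects")
  C <- ncol(peak_r)
  if (is.null(channel_names)) channel_names <- sprintf("Ch %d", seq_len(C))
  tt <- lapply(seq_len(C), function(j) stats::t.test(peak_r[, j]))
  p <- vapply(tt, function(x) x$p.value, 0)
  p_fdr <- fdr_correct(p)
  data.frame(channel = channel_names,
             t_statistic = vapply(tt, function(x) unname(x$statistic), 0),
             p_value = p,
             mean_peak_r = colMeans(peak_r),
             mean_peak_cov = if (is.null(peak_cov)) NA_real_
                             else colMeans(as.matrix(peak_cov)),
             p_fdr = p_fdr,
             significant = p_fdr < alpha)
}

#' Stimulation-versus-silence contrast matrices
#'
#' Pairs every stimulation segment with every silence segment of equal
#' length and computes (i) the Pearson correlation between the two
#' Delta-HbT (or intensity) time courses and (ii) a two-sample t-test
#' p-value on their samples, averaged across channels. Silence segments
#' default to the windows immediately preceding each stimulus onset,
#' length-matched to the stimulation segments.
#'
#' @param rec A `time_series_recording` or channels x samples matrix.
#' @param onsets Stimulus onsets, seconds (default: the recording's
#'   non-silence events).
#' @param segment_s Segment length, seconds (default 2).
#' @param r_threshold Correlation magnitude marked as notable (default
#'   0.25).
#' @param alpha Significance threshold for the p-matrix marks (default
#'   0.05).
#' @param sample_rate Required for matrix input.
#' @return An object of class `contrast_matrices` with `r_matrix`,
#'   `p_matrix` (stimulation x silence), logical `r_marks` / `p_marks`,
#'   and `p_values` (all channel-level p-values, for the histogram).
#' @export
stim_silence_contrast <- function(rec, onsets = NULL, segment_s = 2,
                                  r_threshold = 0.25, alpha = 0.05,
                                  sample_rate = NULL) {
  if (inherits(rec, "time_series_recording")) {
    data <- rec$data
    fs <- rec$sample_rate
    if (is.null(onsets))
      onsets <- rec$events$onset[rec$events$kind != "silence"]
  } else {
    data <- if (is.matrix(rec)) rec else matrix(rec, nrow = 1L)
    fs <- sample_rate
    if (is.null(fs)) stop("sample_rate required for matrix input")
    if (is.null(onsets)) stop("onsets required for matrix input")
  }
  if (!length(onsets)) stop("need at least one stimulation segment")
  nseg <- round(segment_s * fs)
  n <- ncol(data)
  seg_idx <- function(start_s) {
    i0 <- round(start_s * fs) + 1L
    if (i0 < 1L || i0 + nseg - 1L > n) stop("segment escapes the recording")
    i0:(i0 + nseg - 1L)
  }
  stim_idx <- lapply(onsets, seg_idx)
  sil_idx <- lapply(onsets - segment_s, seg_idx)
  S <- length(stim_idx); Z <- length(sil_idx)
  r_mat <- matrix(0, S, Z); p_mat <- matrix(0, S, Z)
  p_all <- numeric(0)
  for (i in seq_len(S)) for (j in seq_len(Z)) {
    rs <- ps <- numeric(nrow(data))
    for (ch in seq_len(nrow(data))) {
      a <- data[ch, stim_idx[[i]]]
      b <- data[ch, sil_idx[[j]]]
      rs[ch] <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
                else stats::cor(a, b)
      ps[ch] <- if (isTRUE(all.equal(a, b))) 1
                else stats::t.test(a, b)$p.value
    }
    r_mat[i, j] <- mean(rs)
    p_mat[i, j] <- mean(ps)
    p_all <- c(p_all, ps)
  }
  dimnames(r_mat) <- dimnames(p_mat) <-
    list(sprintf("stim%d", seq_len(S)), sprintf("sil%d", seq_len(Z)))
  structure(list(r_matrix = r_mat, p_matrix = p_mat,
                 r_marks = abs(r_mat) > r_threshold,
                 p_marks = p_mat < alpha,
                 p_values = p_all,
                 r_threshold = r_threshold, alpha = alpha),
            class = "contrast_matrices")
}

#' Average contrast matrices across subjects
#'
#' @param contrasts List of `contrast_matrices` (one per subject).
#' @param r_threshold,alpha Marking thresholds for the averaged matrices.
#' @return A `contrast_matrices` object with averaged matrices and the
#'   pooled p-values.
#' @export
contrast_average <- function(contrasts, r_threshold = 0.25, alpha = 0.05) {
  stopifnot(length(contrasts) >= 1L,
            all(vapply(contrasts, inherits, TRUE, "contrast_matrices")))
  r_mat <- Reduce(`+`, lapply(contrasts, `[[`, "r_matrix")) / length(contrasts)
  p_mat <- Reduce(`+`, lapply(contrasts, `[[`, "p_matrix")) / length(contrasts)
  structure(list(r_matrix = r_mat, p_matrix = p_mat,
                 r_marks = abs(r_mat) > r_threshold,
                 p_marks = p_mat < alpha,
                 p_values = unlist(lapply(contrasts, `[[`, "p_values")),
                 r_threshold = r_threshold, alpha = alpha),
            class = "contrast_matrices")
}

#' Histogram counts of contrast p-values
#'
#' Bins of width 0.005 over [0, 1], so a bin edge falls exactly at the 0.05
#' significance threshold.
#'
#' @param p Numeric p-values in [0, 1].
#' @param bin_width Bin width (default 0.005).
#' @return Data frame with bin left edge, right edge and count.
#' @export
p_histogram <- function(p, bin_width = 0.005) {
  stopifnot(all(p >= 0 & p <= 1))
  breaks <- seq(0, 1, by = bin_width)
  h <- graphics::hist(p, breaks = breaks, plot = FALSE)
  data.frame(left = breaks[-length(breaks)], right = breaks[-1],
             count = h$counts)
}

#' Spatial repeated-measures ANOVA on response amplitudes
#'
#' One-way repeated-measures ANOVA with channel as the within-subject
#' factor, testing whether response strength differs across the scalp (a
#' localized neural response) or is uniform (a global systemic artifact).
#' Degrees of freedom are (C - 1) and (C - 1)(S - 1); no sphericity
#' correction is applied by default. Post-hoc all-pairs paired t-tests are
#' corrected with Holm's method.
#'
#' @param betas Subjects x channels matrix (complete, no missing cells).
#' @param posthoc Compute the Holm-corrected pairwise matrix (default TRUE).
#' @return An object of class `spatial_anova`: F_value, df_num, df_den,
#'   p_value, and `posthoc` (symmetric channels x channels matrix of
#'   Holm-corrected p-values, NA on the diagonal).
#' @export
spatial_anova <- function(betas, posthoc = TRUE) {
  betas <- as.matrix(betas)
  S <- nrow(betas); C <- ncol(betas)
  if (S < 2L || C < 2L) stop("need at least 2 subjects and 2 channels")
  if (any(!is.finite(betas))) stop("betas must be complete (no missing cells)")
  df_num <- C - 1L
  df_den <- (C - 1L) * (S - 1L)
  grand <- mean(betas)
  ss_channel <- S * sum((colMeans(betas) - grand)^2)
  if (ss_channel < 1e-24 * max(1, grand^2)) {
    F_value <- 0; p_value <- 1
  } else {
    d <- data.frame(y = as.vector(betas),
                    subject = factor(rep(seq_len(S), times = C)),
                    channel = factor(rep(seq_len(C), each = S)))
    fit <- stats::aov(y ~ channel + Error(subject), data = d)
    tab <- summary(fit)[["Error: Within"]][[1]]
    F_value <- tab["channel", "F value"]
    p_value <- tab["channel", "Pr(>F)"]
  }
  ph <- NULL
  if (posthoc) {
    pairs <- utils::combn(C, 2L)
    p_raw <- apply(pairs, 2L, function(ij)
      stats::t.test(betas[, ij[1]], betas[, ij[2]], paired = TRUE)$p.value)
    p_holm <- holm_correct(p_raw)
    ph <- matrix(NA_real_, C, C)
    for (k in seq_len(ncol(pairs))) {
      ph[pairs[1, k], pairs[2, k]] <- p_holm[k]
      ph[pairs[2, k], pairs[1, k]] <- p_holm[k]
    }
    dimnames(ph) <- list(sprintf("Ch %d", seq_len(C)),
                         sprintf("Ch %d", seq_len(C)))
  }
  structure(list(F_value = F_value, df_num = df_num, df_den = df_den,
                 p_value = p_value, posthoc = ph,
                 n_subjects = S, n_channels = C),
            class = "spatial_anova")
}

#' @export
print.spatial_anova <- function(x, ...) {
  cat(sprintf("<spatial_anova> F(%d, %d) = %.4f, p = %.4g\n",
              x$df_num, x$df_den, x$F_value, x$p_value))
  invisible(x)
}

#' Holm step-down multiple-testing correction
#'
#' @param p Numeric p-values in [0, 1].
#' @return Adjusted p-values (monotone, capped at 1), same order as input.
#' @export
holm_correct <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Benjamini-Hochberg step-up false-discovery-rate correction
#'
#' @param p Numeric p-values in [0, 1].
#' @return BH-adjusted p-values, same order as input.
#' @export
fdr_correct <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
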