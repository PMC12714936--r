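# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately re-derive results with the simplest possible
# loops so they share no code with the implementation.

# exhaustive peak finder: strict local maxima above min_height, then greedy
# acceptance by decreasing amplitude (ties: earliest) with pairwise distance
# checks against every already-accepted peak
oracle_find_peaks <- function(x, min_height, min_dist) {
  n <- length(x)
  locmax <- integer(0)
  if (n >= 3L) {
    for (i in 2:(n - 1L))
      if (x[i] > x[i - 1L] && x[i] > x[i + 1L] && x[i] >= min_height)
        locmax <- c(locmax, i)
  }
  if (!length(locmax)) return(integer(0))
  ord <- locmax[order(-x[locmax], locmax)]
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) if (abs(i - j) < min_dist) ok <- FALSE
    if (ok) kept <- c(kept, i)
  }
  sort(kept)
}

# Holm step-down adjusted p-values from the textbook definition
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (k in seq_len(n)) {
    running <- max(running, (n - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, running)
  }
  adj
}

# Benjamini-Hochberg step-up adjusted p-values from the textbook definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  running <- 1
  for (k in n:1) {
    running <- min(running, n / k * ps[k])
    adj[o[k]] <- running
  }
  adj
}

# construct an averaged_waveform object directly (for scoring/SNR tests)
make_wf <- function(values, sample_rate = 16000, baseline_mean = 0,
                    baseline_sd = 1, norm_factor = 1, normalized = TRUE,
                    channel = "EEG01", intensity = 90, n_averaged = 1L) {
  structure(list(values = values,
                 time_ms = (seq_along(values) - 1L) / sample_rate * 1000,
                 channel = channel, intensity = intensity,
                 n_averaged = n_averaged, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, norm_factor = norm_factor,
                 normalized = normalized, sample_rate = sample_rate),
            class = "averaged_waveform")
}

# smooth random waveform with several well-separated bumps
random_waveform <- function(n = 200, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  k <- stats::dnorm(seq(-3, 3, length.out = 15))
  y <- stats::filter(x, k / sum(k), circular = TRUE)
  as.numeric(y / max(abs(y)))
}

# gaussian bump helper on a millisecond time axis
bump <- function(t_ms, center_ms, amp, sd_ms = 0.17) {
  amp * exp(-0.5 * ((t_ms - center_ms) / sd_ms)^2)
}
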