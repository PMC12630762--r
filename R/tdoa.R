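# Waveform-level TDOA measurement: highpass filtering, pairwise
# cross-correlation, and parabolic sub-sample peak interpolation.

# cross-correlation r(lag) = sum_n x[n + lag] * y[n], lags -(N-1)..(N-1)
xcorr_full <- function(x, y) {
  n <- length(x)
  r <- stats::convolve(x, y, conj = TRUE, type = "open")
  list(lags = seq.int(-(n - 1L), n - 1L), r = r)
}

# analytic-signal envelope of a correlation sequence (FFT Hilbert transform);
# removes the carrier oscillation so the peak search cannot slip a cycle on
# narrowband clicks
corr_envelope <- function(r) {
  n <- length(r)
  X <- stats::fft(r)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# sub-sample peak: integer argmax of the correlation envelope, refined by
# log-parabolic interpolation (exact for a Gaussian envelope and exact zero
# offset for symmetric peaks)
parabolic_peak <- function(lags, r) {
  e <- corr_envelope(r)
  k <- which.max(e)
  if (k == 1L || k == length(e)) return(lags[k])
  tri <- e[(k - 1L):(k + 1L)]
  if (any(tri <= 0)) {            # fall back to plain parabola on r
    tri <- r[(k - 1L):(k + 1L)]
    denom <- tri[1] - 2 * tri[2] + tri[3]
    if (denom == 0) return(lags[k])
    return(lags[k] + 0.5 * (tri[1] - tri[3]) / denom)
  }
  lt <- log(tri)
  denom <- lt[1] - 2 * lt[2] + lt[3]
  if (denom == 0) return(lags[k])
  lags[k] + 0.5 * (lt[1] - lt[3]) / denom
}

#' Measure intra-array TDOAs from a 4-channel click window
#'
#' Each channel is highpass filtered (4th-order Butterworth, default cutoff
#' 20 kHz, applied forward-backward) and every hydrophone pair is
#' cross-correlated; the pair TDOA is the correlation-peak lag refined by
#' parabolic sub-sample interpolation. The three-term closure residual
#' tau_12 + tau_23 - tau_13 is reported as a consistency diagnostic.
#'
#' @param window Numeric matrix, samples x 4 channels.
#' @param sample_rate Sampling rate (Hz).
#' @param highpass_cutoff Highpass cutoff (Hz); `0` or `NULL` disables
#'   filtering (useful for very short windows).
#' @param min_window_s Minimum accepted window duration (s); default 50 us,
#'   the correlation window used around each click candidate.
#' @return List of class `tdoa_set` with `tdoas` (length 6,
#'   [tdoa_pairs()] order, seconds), `closure_residual` (s), `valid`
#'   (logical 6), `sample_rate`.
#' @export
measure_tdoa <- function(window, sample_rate, highpass_cutoff = 20e3,
                         min_window_s = 50e-6) {
  window <- as.matrix(window)
  if (ncol(window) != 4L) stop("window must have 4 channels (columns)")
  n <- nrow(window)
  if (n / sample_rate < min_window_s)
    stop(sprintf("window too short: %.1f us < %.1f us",
                 1e6 * n / sample_rate, 1e6 * min_window_s))
  if (all(apply(window, 2, stats::sd) < .Machine$double.eps))
    stop("flat signal: no correlation peak")
  if (!is.null(highpass_cutoff) && highpass_cutoff > 0) {
    if (n <= 30)
      stop("window too short for highpass filtering; pass highpass_cutoff = 0")
    bf <- signal::butter(4, highpass_cutoff / (sample_rate / 2), type = "high")
    window <- apply(window, 2, function(ch)
      signal::filtfilt(bf, ch))
  }
  p <- tdoa_pairs()
  tdoas <- vapply(seq_len(6L), function(k) {
    xc <- xcorr_full(window[, p[k, 1]], window[, p[k, 2]])
    parabolic_peak(xc$lags, xc$r) / sample_rate
  }, numeric(1))
  structure(list(tdoas = tdoas,
                 closure_residual = tdoas[1] + tdoas[4] - tdoas[2],
                 valid = rep(TRUE, 6L),
                 sample_rate = sample_rate),
            class = "tdoa_set")
}
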