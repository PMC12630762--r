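# Cross-array association of echolocation click trains by normalized
# cross-correlation of binned event-time sequences.

# normalized cross-correlation of two binned click trains over integer lags
# r(l) = sum_n a[n] b[n + l] / sqrt(sum a^2 sum b^2); lag > 0 means train b
# occurs later than train a.
train_xcorr <- function(times_a, times_b, bin = 0.02, max_lag = 2) {
  t0 <- min(times_a, times_b)
  t1 <- max(times_a, times_b)
  nb <- max(1L, ceiling((t1 - t0) / bin) + 1L)
  a <- tabulate(pmin(floor((times_a - t0) / bin) + 1L, nb), nb)
  b <- tabulate(pmin(floor((times_b - t0) / bin) + 1L, nb), nb)
  L <- max(1L, round(max_lag / bin))
  denom <- sqrt(sum(a^2) * sum(b^2))
  # FFT correlation padded to a power of two (plain convolve is O(n^2) on
  # awkward lengths); cc[l mod m] = sum_n b[n + l] a[n]
  m <- stats::nextn(nb + L + 1L, 2)
  fa <- stats::fft(c(a, numeric(m - nb)))
  fb <- stats::fft(c(b, numeric(m - nb)))
  cc <- Re(stats::fft(fb * Conj(fa), inverse = TRUE)) / m
  lags <- seq.int(-L, L)
  r <- cc[ifelse(lags >= 0, lags, m + lags) + 1L] / denom
  k <- which.max(r)
  list(peak = r[k], lag = lags[k] * bin, lags = lags * bin, r = r)
}

#' Associate click trains between two arrays
#'
#' Candidate pairings between event-time trains detected on two arrays are
#' scored by the peak normalized cross-correlation of their binned trains
#' over lags up to `max_lag`; pairs at or above `threshold` are accepted
#' greedily in descending peak order with one-to-one assignment.
#'
#' @param trains_a,trains_b Named lists of numeric click-time vectors
#'   (seconds), one element per candidate individual on each array.
#' @param max_lag Maximum |lag| searched (s), default 2.
#' @param threshold Minimum correlation peak to accept a pairing (default
#'   0.5).
#' @param bin Train binning resolution (s), default 0.02 (20 ms).
#' @param segment_s When set, trains are scored on sliding segments of this
#'   duration and a pair's score is its best segment peak. Long trains
#'   recorded on two separated arrays drift in relative lag as the whale
#'   moves (up to ~2 ms per second of track), which smears a whole-train
#'   correlation; windowing restores the peak. `NULL` (default) correlates
#'   whole trains.
#' @param min_segment_clicks Minimum clicks per train segment for the
#'   segment to be scored.
#' @return data.frame with columns `train_a`, `train_b`, `peak`, `lag_s`
#'   (positive when the array-B train lags array A), `anchor_s` (time of
#'   the scored segment; `NA` for whole-train scoring). Zero rows if
#'   nothing associates.
#' @export
associate_click_trains <- function(trains_a, trains_b, max_lag = 2,
                                   threshold = 0.5, bin = 0.02,
                                   segment_s = NULL,
                                   min_segment_clicks = 20) {
  if (!length(trains_a) || !length(trains_b))
    stop("empty train set")
  if (any(!vapply(c(trains_a, trains_b), length, 1L)))
    stop("empty click train")
  if (is.null(names(trains_a))) names(trains_a) <- paste0("A", seq_along(trains_a))
  if (is.null(names(trains_b))) names(trains_b) <- paste0("B", seq_along(trains_b))
  cand <- expand.grid(a = names(trains_a), b = names(trains_b),
                      stringsAsFactors = FALSE)
  score_pair <- function(a, b) {
    if (is.null(segment_s))
      return(c(train_xcorr(a, b, bin = bin, max_lag = max_lag)[c("peak", "lag")],
               anchor = NA_real_))
    t0 <- max(min(a), min(b)); t1 <- min(max(a), max(b))
    best <- list(peak = 0, lag = 0, anchor = NA_real_)
    if (t1 - t0 >= segment_s) {
      for (s0 in seq(t0, t1 - segment_s, by = segment_s)) {
        aa <- a[a >= s0 & a < s0 + segment_s]
        bb <- b[b >= s0 - max_lag & b < s0 + segment_s + max_lag]
        if (length(aa) < min_segment_clicks ||
            length(bb) < min_segment_clicks) next
        x <- train_xcorr(aa, bb, bin = bin, max_lag = max_lag)
        if (x$peak > best$peak)
          best <- list(peak = x$peak, lag = x$lag, anchor = s0 + segment_s / 2)
      }
    }
    best
  }
  sc <- lapply(seq_len(nrow(cand)), function(k)
    score_pair(trains_a[[cand$a[k]]], trains_b[[cand$b[k]]]))
  cand$peak <- vapply(sc, function(s) as.numeric(s$peak), numeric(1))
  cand$lag_s <- vapply(sc, function(s) as.numeric(s$lag), numeric(1))
  cand$anchor_s <- vapply(sc, function(s) as.numeric(s$anchor), numeric(1))
  cand <- cand[order(-cand$peak), , drop = FALSE]
  used_a <- used_b <- character(0)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (cand$peak[k] < threshold) break
    if (cand$a[k] %in% used_a || cand$b[k] %in% used_b) next
    keep[k] <- TRUE
    used_a <- c(used_a, cand$a[k])
    used_b <- c(used_b, cand$b[k])
  }
  out <- cand[keep, , drop = FALSE]
  names(out)[1:2] <- c("train_a", "train_b")
  rownames(out) <- NULL
  out
}
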