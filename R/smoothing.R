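# Track smoothing: constant-velocity Kalman filter followed by a centered
# moving average.

# Forward constant-velocity Kalman filter on irregularly sampled 3D
# positions. State per axis-pair: [position, velocity]; white-acceleration
# process noise with s.d. `process_noise` (m/s^2); per-point measurement
# s.d. in `meas_sd` (n x 3).
kalman_cv_filter <- function(times, positions, meas_sd, process_noise = 0.1) {
  n <- nrow(positions)
  est <- matrix(NA_real_, n, 3)
  # state: (x, y, z, vx, vy, vz)
  dt1 <- times[2] - times[1]
  xhat <- c(positions[1, ], (positions[2, ] - positions[1, ]) / dt1)
  # initial covariance consistent with the two-point velocity estimate
  P <- diag(c(meas_sd[1, ]^2,
              (meas_sd[1, ]^2 + meas_sd[2, ]^2) / dt1^2), 6)
  est[1, ] <- xhat[1:3]
  q2 <- process_noise^2
  H <- cbind(diag(3), matrix(0, 3, 3))
  for (k in 2:n) {
    dt <- times[k] - times[k - 1]
    FF <- diag(6)
    FF[1:3, 4:6] <- diag(dt, 3)
    Qp <- matrix(0, 6, 6)
    Qp[1:3, 1:3] <- diag(q2 * dt^4 / 4, 3)
    Qp[1:3, 4:6] <- Qp[4:6, 1:3] <- diag(q2 * dt^3 / 2, 3)
    Qp[4:6, 4:6] <- diag(q2 * dt^2, 3)
    xhat <- FF %*% xhat
    P <- FF %*% P %*% t(FF) + Qp
    R <- diag(meas_sd[k, ]^2, 3)
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    xhat <- xhat + K %*% (positions[k, ] - H %*% xhat)
    P <- (diag(6) - K %*% H) %*% P
    est[k, ] <- xhat[1:3]
  }
  est
}

# centered moving average with symmetric shrinking half-width at the edges
# (keeps the smoother unbiased on linear segments and preserves length)
moving_average_centered <- function(x, window = 5) {
  n <- length(x)
  h <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)
    mean(x[(i - hh):(i + hh)])
  }, numeric(1))
}

#' Smooth a localized track
#'
#' Applies a constant-velocity Kalman filter (3D position + velocity state)
#' whose per-point measurement noise is taken from the jackknife confidence
#' half-widths (s.d. = CI/2, floored at `ci_floor` meters), then a centered
#' moving average. Output point count equals input point count.
#'
#' @param track data.frame with columns `time`, `x`, `y`, `depth` and
#'   optionally `ci95_x`, `ci95_y`, `ci95_z` (m).
#' @param process_noise White-acceleration process noise s.d. (m/s^2).
#' @param window Moving-average window (points, odd).
#' @param ci_floor Floor on the measurement s.d. (m).
#' @return The input with added columns `x_smooth`, `y_smooth`,
#'   `depth_smooth`.
#' @export
smooth_track <- function(track, process_noise = 0.1, window = 5,
                         ci_floor = 10) {
  if (nrow(track) < 3L) stop("need at least 3 points to smooth a track")
  if (any(diff(track$time) <= 0)) stop("track times must be strictly increasing")
  ci <- cbind(track$ci95_x %||% rep(0, nrow(track)),
              track$ci95_y %||% rep(0, nrow(track)),
              track$ci95_z %||% rep(0, nrow(track)))
  meas_sd <- pmax(ci / 2, ci_floor)
  pos <- cbind(track$x, track$y, track$depth)
  filt <- kalman_cv_filter(track$time, pos, meas_sd, process_noise)
  track$x_smooth <- moving_average_centered(filt[, 1], window)
  track$y_smooth <- moving_average_centered(filt[, 2], window)
  track$depth_smooth <- moving_average_centered(filt[, 3], window)
  track
}
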