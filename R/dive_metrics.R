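# Per-track dive-behavior metrics: encounter segmentation, altitude above
# the seafloor, dive-phase classification, descent angle, swim speeds.

#' Segment detection times into encounters
#'
#' Successive detections belong to the same encounter unless the gap between
#' them strictly exceeds `gap_minutes` (default 30 minutes); a gap of exactly
#' the threshold does not split.
#'
#' @param detection_times Numeric vector of detection times (s); any order.
#' @param gap_minutes Gap threshold in minutes.
#' @return data.frame with one row per encounter: `encounter_id`, `start_s`,
#'   `end_s`, `n_detections`. The attribute `"assignment"` carries the
#'   encounter id of each input time (in input order).
#' @export
segment_encounters <- function(detection_times, gap_minutes = 30) {
  if (!length(detection_times))
    return(structure(data.frame(encounter_id = integer(0), start_s = numeric(0),
                                end_s = numeric(0), n_detections = integer(0)),
                     assignment = integer(0)))
  o <- order(detection_times)
  ts <- detection_times[o]
  gap_s <- gap_minutes * 60
  newenc <- c(TRUE, diff(ts) > gap_s)
  enc_sorted <- cumsum(newenc)
  assignment <- integer(length(ts))
  assignment[o] <- enc_sorted
  out <- data.frame(encounter_id = seq_len(max(enc_sorted)),
                    start_s = tapply(ts, enc_sorted, min),
                    end_s = tapply(ts, enc_sorted, max),
                    n_detections = as.integer(table(enc_sorted)))
  rownames(out) <- NULL
  structure(out, assignment = assignment)
}

#' Altitude above the seafloor along a track
#'
#' Altitude at each point is the depth of the closest bathymetric node minus
#' the whale's depth (bilinear interpolation available behind `method`).
#'
#' @param track data.frame with `x`, `y`, `depth`.
#' @param bathy A [bathymetry()] grid covering the track.
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @return Numeric vector of altitudes (m).
#' @export
altitude_above_seafloor <- function(track, bathy,
                                    method = c("nearest", "bilinear")) {
  bathy_depth_at(bathy, track$x, track$y, method = match.arg(method)) -
    track$depth
}

#' Classify dive phases against the seafloor
#'
#' A track is in its initial descent from the start until it first comes
#' within `threshold_m` of the seafloor (inclusive: altitude exactly at the
#' threshold counts as at depth), after which every point is labeled
#' at-depth — the switch is one-way.
#'
#' @param track data.frame with `x`, `y`, `depth` (time-ordered).
#' @param bathy A [bathymetry()] grid; ignored when `altitudes` is given.
#' @param threshold_m Altitude threshold (m), default 200.
#' @param altitudes Optional precomputed altitudes.
#' @return Character vector of per-point labels, `"initial_descent"` or
#'   `"at_depth"`.
#' @export
classify_phases <- function(track, bathy = NULL, threshold_m = 200,
                            altitudes = NULL) {
  if (is.null(altitudes))
    altitudes <- altitude_above_seafloor(track, bathy)
  n <- length(altitudes)
  first <- which(altitudes <= threshold_m)[1]
  lab <- rep("initial_descent", n)
  if (!is.na(first)) lab[first:n] <- "at_depth"
  lab
}

#' Descent angle of a track
#'
#' Per-segment angles over the initial-descent phase are
#' atan2(-delta depth, horizontal distance) in degrees (negative downward,
#' relative to the sea surface). A Gaussian kernel density (Silverman
#' bandwidth) is evaluated on a 0.1-degree grid over [-90, 90] and its
#' argmax reported as the descent angle; the s.d. is computed over segment
#' angles within 20 degrees of that peak.
#'
#' @param track data.frame with `time`, `x`, `y`, `depth` (smoothed
#'   columns, when present, are preferred).
#' @param phases Optional per-point phase labels from [classify_phases()];
#'   when given, only segments whose both endpoints are `"initial_descent"`
#'   are used.
#' @param min_step_m Minimum 3D displacement per angle segment (m).
#'   Successive points are aggregated until they are at least this far
#'   apart, which keeps segment angles meaningful when per-point position
#'   noise exceeds the per-sample displacement. 0 (default) uses every
#'   successive pair.
#' @return List with `angle_deg` (KDE peak), `sd_deg`, `n_segments`,
#'   `angles` (per-segment values).
#' @export
descent_angle <- function(track, phases = NULL, min_step_m = 0) {
  px <- track$x_smooth %||% track$x
  py <- track$y_smooth %||% track$y
  pz <- track$depth_smooth %||% track$depth
  pts <- seq_len(nrow(track))
  if (!is.null(phases)) pts <- pts[phases == "initial_descent"]
  if (length(pts) < 2L) stop("need at least 2 descent-phase points")
  px <- px[pts]; py <- py[pts]; pz <- pz[pts]
  if (min_step_m > 0) {
    keep_idx <- 1L
    last <- 1L
    for (k in 2:length(px)) {
      d3 <- sqrt((px[k] - px[last])^2 + (py[k] - py[last])^2 +
                   (pz[k] - pz[last])^2)
      if (d3 >= min_step_m) { keep_idx <- c(keep_idx, k); last <- k }
    }
    if (length(keep_idx) < 2L) stop("track too short for min_step_m")
    px <- px[keep_idx]; py <- py[keep_idx]; pz <- pz[keep_idx]
  }
  dh <- sqrt(diff(px)^2 + diff(py)^2)
  dz <- diff(pz)
  keep <- dh > 0 | dz != 0
  if (!any(keep)) stop("all descent segments have zero length")
  ang <- rad2deg(atan2(-dz[keep], dh[keep]))
  if (length(ang) < 2L || stats::sd(ang) == 0) {
    peak <- ang[1]
  } else {
    de <- stats::density(ang, bw = "nrd0", from = -90, to = 90, n = 1801L)
    peak <- de$x[which.max(de$y)]
  }
  near <- ang[abs(ang - peak) <= 20]
  list(angle_deg = peak,
       sd_deg = if (length(near) > 1L) stats::sd(near) else 0,
       n_segments = length(ang),
       angles = ang)
}

#' Median swim speeds per dive phase
#'
#' Per-step speed is the 3D Euclidean distance between successive smoothed
#' positions divided by the time step. Medians are reported per phase;
#' phases with less than the minimum duration (descent 5 min, at-depth
#' 10 min by default) are reported as `NA`.
#'
#' @param track data.frame with `time` plus smoothed coordinates
#'   (`x_smooth`, `y_smooth`, `depth_smooth`; falls back to raw `x`, `y`,
#'   `depth` when absent).
#' @param phases Per-point phase labels ([classify_phases()]).
#' @param min_descent_s,min_at_depth_s Minimum phase durations (s).
#' @return List with `descent_mps`, `at_depth_mps` (medians, `NA` when the
#'   phase is too short or absent) and `speeds` (per-step values with the
#'   phase of each step).
#' @export
swim_speeds <- function(track, phases, min_descent_s = 300,
                        min_at_depth_s = 600) {
  sx <- track$x_smooth %||% track$x
  sy <- track$y_smooth %||% track$y
  sz <- track$depth_smooth %||% track$depth
  dt <- diff(track$time)
  if (any(dt <= 0)) stop("zero or negative time step between points")
  sp <- sqrt(diff(sx)^2 + diff(sy)^2 + diff(sz)^2) / dt
  step_phase <- phases[-length(phases)]
  dur <- function(ph) {
    tt <- track$time[phases == ph]
    if (length(tt) < 2L) 0 else max(tt) - min(tt)
  }
  med <- function(ph, min_s) {
    if (dur(ph) < min_s) return(NA_real_)
    v <- sp[step_phase == ph & phases[-1] == ph]
    if (!length(v)) NA_real_ else stats::median(v)
  }
  list(descent_mps = med("initial_descent", min_descent_s),
       at_depth_mps = med("at_depth", min_at_depth_s),
       speeds = data.frame(time = track$time[-1], speed_mps = sp,
                           phase = step_phase))
}

#' Per-track metrics table
#'
#' Convenience wrapper producing one summary row per track: phase durations,
#' descent angle, median speeds, median at-depth altitude.
#'
#' @param tracks Named list of track data.frames (`time`, `x`, `y`, `depth`,
#'   optionally smoothed columns).
#' @param bathy A [bathymetry()] grid.
#' @param encounter_ids Optional named vector mapping whale id to encounter.
#' @param min_step_m Passed to [descent_angle()]; use ~20 m for localized
#'   tracks whose per-point noise exceeds the inter-click displacement.
#' @inheritParams classify_phases
#' @return data.frame, one row per track.
#' @export
track_metrics <- function(tracks, bathy, threshold_m = 200,
                          encounter_ids = NULL, min_step_m = 0) {
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    alt <- altitude_above_seafloor(tr, bathy)
    ph <- classify_phases(tr, altitudes = alt, threshold_m = threshold_m)
    ang <- tryCatch(descent_angle(tr, ph, min_step_m = min_step_m),
                    error = function(e) NULL)
    sp <- swim_speeds(tr, ph)
    dur <- function(p) {
      tt <- tr$time[ph == p]
      if (length(tt) < 2L) 0 else max(tt) - min(tt)
    }
    data.frame(whale_id = id,
               encounter_id = if (is.null(encounter_ids)) NA_integer_
                              else encounter_ids[[id]],
               descent_duration_s = dur("initial_descent"),
               at_depth_duration_s = dur("at_depth"),
               descent_angle_deg = if (is.null(ang)) NA_real_ else ang$angle_deg,
               descent_angle_sd_deg = if (is.null(ang)) NA_real_ else ang$sd_deg,
               descent_speed_mps = sp$descent_mps,
               at_depth_speed_mps = sp$at_depth_mps,
               median_altitude_m = stats::median(alt[ph == "at_depth"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
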