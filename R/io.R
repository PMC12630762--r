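# Delimited-table I/O for detections and tracks, presence summaries, and a
# minimal lat/lon <-> local-ENU helper. All files are UTF-8 CSV with a
# header row and '.' decimal separator.

detection_columns <- c("array_id", "arrival_time_s", "rl_db",
                       "tdoa_12", "tdoa_13", "tdoa_14",
                       "tdoa_23", "tdoa_24", "tdoa_34")

#' Write a detections table
#'
#' @param detections data.frame as produced by [propagate_and_detect()] or
#'   with the documented columns (`array_id`, `arrival_time_s`, `rl_db`,
#'   `tdoa_12` ... `tdoa_34`, optional `truth_whale_id`).
#' @param path Output CSV path.
#' @export
write_detections <- function(detections, path) {
  d <- detections
  # accept the internal simulator column names as well
  ren <- c(arrival_time = "arrival_time_s", received_level = "rl_db",
           whale_id = "truth_whale_id")
  for (nm in names(ren))
    if (nm %in% names(d) && !(ren[[nm]] %in% names(d)))
      names(d)[names(d) == nm] <- ren[[nm]]
  missing <- setdiff(detection_columns, names(d))
  if (length(missing))
    stop("detections table is missing columns: ",
         paste(missing, collapse = ", "))
  front <- c(detection_columns,
             intersect("truth_whale_id", names(d)))
  d <- d[, c(front, setdiff(names(d), front)), drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Read a detections table
#'
#' Tolerant CSV reader: required columns are validated by name, unknown
#' columns are preserved with a warning, and malformed numeric cells are
#' reported with their row and column.
#'
#' @param path CSV path.
#' @return data.frame with the documented detection columns.
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(detection_columns, names(d))
  if (length(missing))
    stop("detections file ", path, " is missing columns: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(d), c(detection_columns, "truth_whale_id"))
  if (length(extra))
    warning("unknown columns preserved: ", paste(extra, collapse = ", "))
  numcols <- setdiff(detection_columns, "array_id")
  for (nm in numcols) {
    v <- suppressWarnings(as.numeric(d[[nm]]))
    bad <- which(is.na(v) & nzchar(d[[nm]]))
    if (length(bad))
      stop(sprintf("malformed numeric value '%s' in column %s, row %d",
                   d[[nm]][bad[1]], nm, bad[1]))
    d[[nm]] <- v
  }
  d
}

track_columns <- c("whale_id", "time_s", "x_m", "y_m", "depth_m",
                   "ci95_x_m", "ci95_y_m", "ci95_z_m",
                   "x_smooth_m", "y_smooth_m", "depth_smooth_m")

#' Write a localized track table
#'
#' @param track data.frame with internal track columns (`whale_id`, `time`,
#'   `x`, `y`, `depth`, `ci95_*`, `*_smooth`) or already in file layout.
#' @param path Output CSV path.
#' @export
write_tracks <- function(track, path) {
  d <- track
  ren <- c(time = "time_s", x = "x_m", y = "y_m", depth = "depth_m",
           ci95_x = "ci95_x_m", ci95_y = "ci95_y_m", ci95_z = "ci95_z_m",
           x_smooth = "x_smooth_m", y_smooth = "y_smooth_m",
           depth_smooth = "depth_smooth_m")
  for (nm in names(ren))
    if (nm %in% names(d) && !(ren[[nm]] %in% names(d)))
      names(d)[names(d) == nm] <- ren[[nm]]
  missing <- setdiff(track_columns, names(d))
  if (length(missing))
    stop("track table is missing columns: ", paste(missing, collapse = ", "))
  utils::write.csv(d[, track_columns], path, row.names = FALSE, quote = FALSE)
}

#' Read a localized track table written by [write_tracks()]
#'
#' @param path CSV path.
#' @return data.frame with internal column names (`time`, `x`, `y`,
#'   `depth`, ...).
#' @export
read_tracks <- function(path) {
  d <- utils::read.csv(path)
  missing <- setdiff(track_columns, names(d))
  if (length(missing))
    stop("track file is missing columns: ", paste(missing, collapse = ", "))
  names(d) <- sub("_m$", "", sub("_s$", "", names(d)))
  names(d)[names(d) == "time"] <- "time"
  d
}

#' Presence summary over effort bins
#'
#' Fraction of effort bins (e.g. minutes or days) containing at least one
#' detection — the standard click-positive presence metric.
#'
#' @param detection_times Numeric detection times (s).
#' @param effort data.frame with `start_s`, `end_s` effort intervals.
#' @param bin_s Bin width in seconds (60 for click-positive minutes, 86400
#'   for click-positive days).
#' @return List with `fraction` (in [0, 1]), `positive_bins`, `total_bins`.
#' @export
presence_summary <- function(detection_times, effort, bin_s = 60) {
  stopifnot(is.data.frame(effort), all(c("start_s", "end_s") %in% names(effort)))
  if (!nrow(effort) || sum(effort$end_s - effort$start_s) <= 0)
    stop("zero effort: no recording intervals")
  total <- 0L; positive <- 0L
  for (k in seq_len(nrow(effort))) {
    edges <- seq(effort$start_s[k], effort$end_s[k], by = bin_s)
    if (edges[length(edges)] < effort$end_s[k])
      edges <- c(edges, effort$end_s[k])
    nb <- length(edges) - 1L
    total <- total + nb
    tt <- detection_times[detection_times >= effort$start_s[k] &
                            detection_times <= effort$end_s[k]]
    if (length(tt)) {
      ib <- pmin(findInterval(tt, edges, rightmost.closed = TRUE), nb)
      positive <- positive + length(unique(ib))
    }
  }
  list(fraction = positive / total, positive_bins = positive,
       total_bins = total)
}

#' Convert longitude/latitude to local ENU meters
#'
#' Simple equirectangular approximation about a reference point; adequate
#' for the few-kilometer scenes handled here. The inverse is
#' [enu_to_lonlat()].
#'
#' @param lon,lat Degrees.
#' @param ref Reference `c(lon, lat)` mapped to (0, 0).
#' @return Matrix with columns `x` (east, m), `y` (north, m).
#' @export
lonlat_to_enu <- function(lon, lat, ref) {
  R <- 6371008.8
  x <- deg2rad(lon - ref[1]) * R * cos(deg2rad(ref[2]))
  y <- deg2rad(lat - ref[2]) * R
  cbind(x = x, y = y)
}

#' @rdname lonlat_to_enu
#' @param x,y Local ENU meters.
#' @export
enu_to_lonlat <- function(x, y, ref) {
  R <- 6371008.8
  cbind(lon = ref[1] + rad2deg(x / (R * cos(deg2rad(ref[2])))),
        lat = ref[2] + rad2deg(y / R))
}
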