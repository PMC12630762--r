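# Group size and coordination metrics: pairs distance, lane distance,
# closest-approach lags, single-linkage subgrouping, track-density maps.

#' Group size of an encounter across two arrays
#'
#' Counts distinct individuals in the union of the two arrays' identities
#' after merging cross-array pairings; a whale recorded on only one array
#' still counts.
#'
#' @param ids_a,ids_b Character vectors of individual identities seen on
#'   each array during the encounter.
#' @param pairings data.frame with columns `train_a`, `train_b` (as from
#'   [associate_click_trains()]) giving cross-array identity merges; may
#'   have zero rows.
#' @return Integer group size.
#' @export
group_size <- function(ids_a, ids_b, pairings = NULL) {
  ids_a <- unique(as.character(ids_a))
  ids_b <- unique(as.character(ids_b))
  if (is.null(pairings) || !nrow(pairings))
    return(length(ids_a) + length(ids_b))
  if (anyDuplicated(pairings$train_a) || anyDuplicated(pairings$train_b))
    stop("inconsistent pairing: an identity is paired more than once")
  matched_b <- pairings$train_b[pairings$train_a %in% ids_a &
                                  pairings$train_b %in% ids_b]
  length(ids_a) + length(setdiff(ids_b, matched_b))
}

#' Per-minute pairs distance between two tracked whales
#'
#' 3D Euclidean distance between time-matched points of the two tracks
#' (nearest-sample matching within `match_tol` seconds), averaged per
#' wall-clock minute bin. Bins exist only where both whales have matched
#' points.
#'
#' @param track_a,track_b data.frames with `time`, `x`, `y`, `depth` (or
#'   smoothed columns, which are preferred when present).
#' @param match_tol Maximum time mismatch for a pair of samples (s).
#' @param bin_s Averaging bin width (s), default one minute.
#' @return data.frame with `minute` (bin start, s), `mean_distance_m`, `n`.
#' @export
pairs_distance <- function(track_a, track_b, match_tol = 5, bin_s = 60) {
  ca <- track_coords(track_a); cb <- track_coords(track_b)
  if (!nrow(ca) || !nrow(cb) ||
      min(cb$time) > max(ca$time) + match_tol ||
      min(ca$time) > max(cb$time) + match_tol)
    return(data.frame(minute = numeric(0), mean_distance_m = numeric(0),
                      n = integer(0)))
  j <- nearest_index(cb$time, ca$time)
  dtm <- abs(cb$time[j] - ca$time)
  ok <- dtm <= match_tol
  if (!any(ok))
    return(data.frame(minute = numeric(0), mean_distance_m = numeric(0),
                      n = integer(0)))
  d <- sqrt((ca$x[ok] - cb$x[j][ok])^2 + (ca$y[ok] - cb$y[j][ok])^2 +
              (ca$z[ok] - cb$z[j][ok])^2)
  bins <- floor(ca$time[ok] / bin_s) * bin_s
  agg <- tapply(d, bins, mean)
  data.frame(minute = as.numeric(names(agg)),
             mean_distance_m = as.numeric(agg),
             n = as.integer(table(bins)))
}

# pull (possibly smoothed) coordinates with z up from a track table
track_coords <- function(tr) {
  data.frame(time = tr$time,
             x = tr$x_smooth %||% tr$x,
             y = tr$y_smooth %||% tr$y,
             z = -(tr$depth_smooth %||% tr$depth))
}

# index of nearest value in sorted vector `ref` for each x
nearest_index <- function(ref, x) {
  i <- findInterval(x, ref)
  i0 <- pmax(i, 1L)
  i1 <- pmin(i + 1L, length(ref))
  ifelse(abs(x - ref[i0]) <= abs(ref[i1] - x), i0, i1)
}

#' Resample a track to uniform arc-length spacing
#'
#' Linear interpolation of the 3D polyline at equally spaced cumulative
#' chord lengths.
#'
#' @param track data.frame with `x`, `y`, `depth` (smoothed columns
#'   preferred).
#' @param step Arc-length spacing (m), default 1.
#' @return data.frame with `s` (arc length), `x`, `y`, `z` (z up).
#' @export
resample_arclength <- function(track, step = 1) {
  co <- track_coords(track)
  if (nrow(co) < 2L) stop("need at least 2 points to resample a track")
  seg <- sqrt(diff(co$x)^2 + diff(co$y)^2 + diff(co$z)^2)
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) stop("zero-length track")
  keep <- c(TRUE, seg > 0)
  s <- s[keep]; co <- co[keep, , drop = FALSE]
  ss <- seq(0, s[length(s)], by = step)
  data.frame(s = ss,
             x = stats::approx(s, co$x, xout = ss)$y,
             y = stats::approx(s, co$y, xout = ss)$y,
             z = stats::approx(s, co$z, xout = ss)$y)
}

#' Lane distance between two tracks
#'
#' Time-free proximity of two swim paths: both smoothed tracks are
#' interpolated to 1 m arc-length bins, each point of track A is matched to
#' its spatially nearest point anywhere on track B, and the resulting
#' distances are averaged over consecutive 10 m arc-length bins along A.
#'
#' @param track_a,track_b data.frames with `x`, `y`, `depth`.
#' @param step Interpolation spacing (m).
#' @param bin Averaging bin length along track A (m).
#' @return data.frame with `bin_start_m` (arc length along A),
#'   `mean_distance_m`, `n`.
#' @export
lane_distance <- function(track_a, track_b, step = 1, bin = 10) {
  ra <- resample_arclength(track_a, step)
  rb <- resample_arclength(track_b, step)
  d <- nearest_point_distance(as.matrix(ra[, c("x", "y", "z")]),
                              as.matrix(rb[, c("x", "y", "z")]))
  bins <- floor(ra$s / bin) * bin
  agg <- tapply(d, bins, mean)
  data.frame(bin_start_m = as.numeric(names(agg)),
             mean_distance_m = as.numeric(agg),
             n = as.integer(table(bins)))
}

# min distance from each row of A to any row of B (chunked brute force)
nearest_point_distance <- function(A, B, chunk = 2000L) {
  n <- nrow(A)
  out <- numeric(n)
  Bt <- t(B)
  b2 <- colSums(Bt^2)
  for (s0 in seq(1L, n, by = chunk)) {
    s1 <- min(s0 + chunk - 1L, n)
    Ak <- A[s0:s1, , drop = FALSE]
    d2 <- outer(rowSums(Ak^2), b2, `+`) - 2 * Ak %*% Bt
    out[s0:s1] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Time lag at the closest spatial approach of two tracks
#'
#' Finds the pair of points (one per track) minimizing 3D distance over all
#' pairs and returns the absolute difference of their timestamps.
#'
#' @param track_a,track_b data.frames with `time`, `x`, `y`, `depth`.
#' @return List with `lag_s`, `distance_m`, `t_a`, `t_b`.
#' @export
closest_approach_lag <- function(track_a, track_b) {
  ca <- track_coords(track_a); cb <- track_coords(track_b)
  if (!nrow(ca) || !nrow(cb)) stop("empty track")
  A <- as.matrix(ca[, c("x", "y", "z")])
  B <- as.matrix(cb[, c("x", "y", "z")])
  best <- c(Inf, NA, NA)
  chunk <- 2000L
  Bt <- t(B); b2 <- colSums(Bt^2)
  for (s0 in seq(1L, nrow(A), by = chunk)) {
    s1 <- min(s0 + chunk - 1L, nrow(A))
    Ak <- A[s0:s1, , drop = FALSE]
    d2 <- outer(rowSums(Ak^2), b2, `+`) - 2 * Ak %*% Bt
    k <- arrayInd(which.min(d2), dim(d2))
    if (d2[k] < best[1]) best <- c(d2[k], s0 + k[1] - 1L, k[2])
  }
  list(lag_s = abs(ca$time[best[2]] - cb$time[best[3]]),
       distance_m = sqrt(max(best[1], 0)),
       t_a = ca$time[best[2]], t_b = cb$time[best[3]])
}

#' Subgroup whales within an encounter by single-linkage clustering
#'
#' Inter-whale distance is the unweighted mean of per-minute pairs
#' distances over shared minutes; pairs whose tracks do not temporally
#' overlap within `overlap_minutes` are assigned infinite distance (forcing
#' separate subgroups). A single-linkage tree over these distances is cut
#' at `distance_cutoff` (whales merge while linkage distance is at or below
#' the cutoff).
#'
#' @param tracks Named list of track data.frames (`time`, `x`, `y`,
#'   `depth`).
#' @param distance_cutoff Cluster cut height (m), default 1000.
#' @param overlap_minutes Maximum allowed temporal gap between two tracks
#'   for a finite distance (min), default 10.
#' @param distances Optional precomputed symmetric distance matrix (whales
#'   as dimnames); overrides computation from tracks.
#' @return List with `labels` (named integer subgroup per whale),
#'   `n_subgroups`, `mean_size`, `distance` (matrix), `tree` (hclust or
#'   NULL for fewer than 2 whales).
#' @export
find_subgroups <- function(tracks = NULL, distance_cutoff = 1000,
                           overlap_minutes = 10, distances = NULL) {
  if (is.null(distances)) {
    ids <- names(tracks)
    nw <- length(ids)
    D <- matrix(Inf, nw, nw, dimnames = list(ids, ids))
    diag(D) <- 0
    if (nw >= 2L) {
      for (i in seq_len(nw - 1L)) for (j in (i + 1L):nw) {
        ta <- range(tracks[[i]]$time); tb <- range(tracks[[j]]$time)
        gap <- max(ta[1], tb[1]) - min(ta[2], tb[2])
        if (gap > overlap_minutes * 60) next       # no overlap within rule
        pd <- pairs_distance(tracks[[i]], tracks[[j]])
        if (nrow(pd)) {
          D[i, j] <- D[j, i] <- mean(pd$mean_distance_m)
        } else {
          # overlap within the rule but no simultaneous samples: use the
          # distance at the temporally closest pair of points
          ci <- track_coords(tracks[[i]]); cj <- track_coords(tracks[[j]])
          if (ta[2] <= tb[1]) {
            pi_ <- ci[nrow(ci), ]; pj_ <- cj[1, ]
          } else {
            pi_ <- ci[1, ]; pj_ <- cj[nrow(cj), ]
          }
          D[i, j] <- D[j, i] <- sqrt((pi_$x - pj_$x)^2 + (pi_$y - pj_$y)^2 +
                                       (pi_$z - pj_$z)^2)
        }
      }
    }
    distances <- D
  } else {
    distances <- as.matrix(distances)
    ids <- rownames(distances) %||% paste0("w", seq_len(nrow(distances)))
    dimnames(distances) <- list(ids, ids)
  }
  nw <- nrow(distances)
  if (!is.finite(distance_cutoff) && distance_cutoff > 0) {
    labels <- stats::setNames(rep(1L, nw), ids)
    return(list(labels = labels, n_subgroups = 1L, mean_size = nw,
                distance = distances, tree = NULL))
  }
  if (nw == 1L) {
    labels <- stats::setNames(1L, ids)
    return(list(labels = labels, n_subgroups = 1L, mean_size = 1,
                distance = distances, tree = NULL))
  }
  # hclust cannot take Inf: substitute a finite sentinel above the cutoff
  Df <- distances
  finite_max <- suppressWarnings(max(Df[is.finite(Df)], na.rm = TRUE))
  sentinel <- max(finite_max, distance_cutoff) * 10 + 10
  Df[!is.finite(Df)] <- sentinel
  tree <- stats::hclust(stats::as.dist(Df), method = "single")
  labels <- stats::cutree(tree, h = distance_cutoff)
  sizes <- table(labels)
  list(labels = labels,
       n_subgroups = length(sizes),
       mean_size = mean(sizes),
       distance = distances,
       tree = tree)
}

#' Track-density grid
#'
#' Counts, in square horizontal bins (default 10 m), the number of distinct
#' tracked whales whose track passes through each bin (a whale counts at
#' most once per bin). Tracks are densified by linear interpolation so that
#' consecutive samples are closer than a quarter bin, which makes bin
#' membership insensitive to the track sampling rate.
#'
#' @param tracks Named list of track data.frames (`x`, `y`; smoothed
#'   columns preferred).
#' @param bin_size Bin edge length (m).
#' @param extent Optional `c(xmin, xmax, ymin, ymax)`; default covers all
#'   tracks.
#' @param densify If `FALSE`, use the raw samples only.
#' @return List with `x_edges`, `y_edges`, `counts` (matrix, x by y).
#' @export
track_density <- function(tracks, bin_size = 10, extent = NULL,
                          densify = TRUE) {
  pts <- lapply(tracks, function(tr) {
    co <- track_coords(tr)
    if (densify && nrow(co) > 1L) {
      seg <- sqrt(diff(co$x)^2 + diff(co$y)^2)
      nsub <- pmax(1L, ceiling(seg / (bin_size / 4)))
      idx <- rep(seq_len(nrow(co) - 1L), nsub)
      frac <- unlist(lapply(nsub, function(m) (seq_len(m) - 1L) / m))
      data.frame(x = co$x[idx] + frac * diff(co$x)[idx],
                 y = co$y[idx] + frac * diff(co$y)[idx]) |>
        rbind(data.frame(x = co$x[nrow(co)], y = co$y[nrow(co)]))
    } else co[, c("x", "y")]
  })
  if (is.null(extent)) {
    allx <- unlist(lapply(pts, `[[`, "x"))
    ally <- unlist(lapply(pts, `[[`, "y"))
    if (!length(allx)) {
      xe <- c(0, bin_size); ye <- c(0, bin_size)
      return(list(x_edges = xe, y_edges = ye,
                  counts = matrix(0L, 1, 1)))
    }
    extent <- c(floor(min(allx) / bin_size) * bin_size,
                ceiling(max(allx) / bin_size + 1e-9) * bin_size,
                floor(min(ally) / bin_size) * bin_size,
                ceiling(max(ally) / bin_size + 1e-9) * bin_size)
  }
  xe <- seq(extent[1], extent[2], by = bin_size)
  ye <- seq(extent[3], extent[4], by = bin_size)
  nx <- length(xe) - 1L; ny <- length(ye) - 1L
  counts <- matrix(0L, nx, ny)
  for (p in pts) {
    ok <- p$x >= extent[1] & p$x <= extent[2] &
          p$y >= extent[3] & p$y <= extent[4]
    if (!any(ok)) next
    ix <- pmin(pmax(findInterval(p$x[ok], xe, rightmost.closed = TRUE), 1L), nx)
    iy <- pmin(pmax(findInterval(p$y[ok], ye, rightmost.closed = TRUE), 1L), ny)
    hit <- unique((iy - 1L) * nx + ix)
    counts[hit] <- counts[hit] + 1L
  }
  list(x_edges = xe, y_edges = ye, counts = counts)
}
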