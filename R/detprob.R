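# Monte Carlo model of the probability that an echolocation click is
# detected on both 4-hydrophone arrays, binned over the modeled area.

#' Off-axis attenuation of a directional click
#'
#' Circular-piston beam pattern: attenuation(theta) =
#' -20 log10 |2 J1(x) / x| with x = ka sin(theta) and the piston size
#' inferred from the directivity index via ka = 10^(DI/20) (large-ka
#' approximation). Attenuation is capped (default 40 dB, also applied in
#' the back hemisphere where the piston model is not meaningful). A
#' directivity index of 0 models an omnidirectional source (0 dB loss at
#' every angle).
#'
#' @param theta_deg Off-axis angle(s), degrees in [0, 180].
#' @param directivity_index Directivity index (dB, >= 0); recycled.
#' @param cap_db Maximum attenuation (dB).
#' @return Attenuation in dB (>= 0).
#' @export
off_axis_attenuation <- function(theta_deg, directivity_index, cap_db = 40) {
  n <- max(length(theta_deg), length(directivity_index))
  theta_deg <- rep_len(theta_deg, n)
  di <- rep_len(directivity_index, n)
  if (any(di < 0)) stop("directivity_index must be >= 0")
  ka <- 10^(di / 20)
  x <- ka * sin(deg2rad(theta_deg))
  att <- numeric(n)
  nz <- abs(x) > 1e-12
  att[nz] <- -20 * log10(abs(2 * besselJ(abs(x[nz]), 1) / x[nz]))
  att[di == 0] <- 0
  att[theta_deg > 90 & di > 0] <- cap_db
  pmin(pmax(att, 0), cap_db)
}

#' Detection-probability simulation configuration
#'
#' Defaults follow the study design: 10,000 echolocating whales per
#' iteration placed in an 8 km by 8 km area gridded at 100 m, peak-to-peak
#' source levels between 221 and 223 dB re 1 uPa, directivity indices
#' between 23 and 25 dB, a 112 dB pp detection threshold on both arrays,
#' and 135 iterations (a 3 source-level x 3 directivity grid with 15
#' replicate seeds each).
#'
#' @param n_whales Simulated whales per iteration.
#' @param area Length-2 area extent (m), centered on the array midpoint.
#' @param bin_size Grid bin size (m); must divide both area dimensions.
#' @param source_level_range,directivity_range Parameter ranges (dB).
#' @param threshold_db Both-array detection threshold (dB pp).
#' @param n_sl,n_di,n_replicates Iteration grid: `n_sl * n_di *
#'   n_replicates` iterations with source level / directivity on a regular
#'   grid over the ranges.
#' @param depth_placement List: `list(kind = "uniform_altitude", min, max)`
#'   (m above local seafloor, the default 50-250) or
#'   `list(kind = "fixed", depth)` (m).
#' @param pitch List: `list(kind = "fixed", value)` degrees (default 0,
#'   horizontal acoustic axis) or `list(kind = "uniform", min, max)`.
#' @param beam `"piston"` or `"omni"`.
#' @export
detprob_config <- function(n_whales = 10000, area = c(8000, 8000),
                           bin_size = 100,
                           source_level_range = c(221, 223),
                           directivity_range = c(23, 25),
                           threshold_db = 112,
                           n_sl = 3, n_di = 3, n_replicates = 15,
                           depth_placement = list(kind = "uniform_altitude",
                                                  min = 50, max = 250),
                           pitch = list(kind = "fixed", value = 0),
                           beam = c("piston", "omni")) {
  beam <- match.arg(beam)
  stopifnot(n_whales > 0, all(area > 0), bin_size > 0,
            diff(source_level_range) >= 0, diff(directivity_range) >= 0)
  if (any(abs(area / bin_size - round(area / bin_size)) > 1e-9))
    stop("bin_size must divide both area dimensions")
  as.list(environment())
}

# iteration parameter grid: n_sl x n_di x n_replicates rows
iteration_params <- function(config, seed = 1) {
  sl <- if (config$n_sl == 1) mean(config$source_level_range) else
    seq(config$source_level_range[1], config$source_level_range[2],
        length.out = config$n_sl)
  di <- if (config$n_di == 1) mean(config$directivity_range) else
    seq(config$directivity_range[1], config$directivity_range[2],
        length.out = config$n_di)
  g <- expand.grid(source_level = sl, directivity = di,
                   replicate = seq_len(config$n_replicates))
  g$seed <- derive_seeds(seed, nrow(g))
  g
}

#' Run one detection-probability Monte Carlo iteration
#'
#' Places `n_whales` whales uniformly in the modeled area with uniform
#' random heading, depth per the configured placement, and the iteration's
#' source level and directivity. A whale's click is detected when its
#' received level, RL = SL - TL(r) - off-axis attenuation, is at or above
#' the threshold on BOTH arrays.
#'
#' @param config A [detprob_config()].
#' @param arrays List of two [array_geometry()] objects.
#' @param bathy A [bathymetry()] grid (used by altitude-based placement).
#' @param env A [make_environment()].
#' @param tl_model TL function ([tl_spherical()] or [tl_from_table()]).
#' @param seed Iteration seed.
#' @param source_level,directivity Iteration parameter values (dB); default
#'   the range midpoints.
#' @param center Optional grid center `c(x, y)` (m); default is the mean of
#'   the array positions. Fix it when comparing runs with different array
#'   subsets on a common grid.
#' @return A `probability_grid`: list with `x_edges`, `y_edges`, `detected`,
#'   `total` (bin count matrices), `p` (probability, `NA` in empty bins).
#' @export
run_detection_iteration <- function(config, arrays, bathy, env,
                                    tl_model = tl_spherical(), seed = 1,
                                    source_level = NULL, directivity = NULL,
                                    center = NULL) {
  source_level <- source_level %||% mean(config$source_level_range)
  directivity <- directivity %||% mean(config$directivity_range)
  ctr <- center %||%
    colMeans(do.call(rbind, lapply(arrays, function(a) a$origin[1:2])))
  half <- config$area / 2
  with_seed(seed, {
    n <- config$n_whales
    x <- stats::runif(n, ctr[1] - half[1], ctr[1] + half[1])
    y <- stats::runif(n, ctr[2] - half[2], ctr[2] + half[2])
    heading <- stats::runif(n, 0, 2 * pi)
    pitch <- switch(config$pitch$kind,
      fixed = rep(deg2rad(config$pitch$value), n),
      uniform = deg2rad(stats::runif(n, config$pitch$min, config$pitch$max)),
      stop("unknown pitch kind"))
    depth <- switch(config$depth_placement$kind,
      fixed = rep(config$depth_placement$depth, n),
      uniform_altitude = {
        fl <- bathy_depth_at(bathy, pmin(pmax(x, min(bathy$x)), max(bathy$x)),
                             pmin(pmax(y, min(bathy$y)), max(bathy$y)))
        fl - stats::runif(n, config$depth_placement$min,
                          config$depth_placement$max)
      },
      stop("unknown depth_placement kind"))
    axis <- cbind(cos(pitch) * sin(heading), cos(pitch) * cos(heading),
                  sin(pitch))
    detected_all <- rep(TRUE, n)
    for (geom in arrays) {
      dvec <- cbind(geom$origin[1] - x, geom$origin[2] - y,
                    geom$origin[3] - (-depth))
      r <- sqrt(rowSums(dvec^2))
      cosang <- rowSums(axis * dvec) / r
      theta <- rad2deg(acos(pmin(pmax(cosang, -1), 1)))
      att <- if (config$beam == "omni") 0 else
        off_axis_attenuation(theta, directivity)
      rl <- source_level - tl_model(r, depth, -geom$origin[3]) - att
      detected_all <- detected_all & (rl >= config$threshold_db)
    }
    xe <- seq(ctr[1] - half[1], ctr[1] + half[1], by = config$bin_size)
    ye <- seq(ctr[2] - half[2], ctr[2] + half[2], by = config$bin_size)
    ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L),
               length(xe) - 1L)
    iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1L),
               length(ye) - 1L)
    nx <- length(xe) - 1L; ny <- length(ye) - 1L
    lin <- (iy - 1L) * nx + ix
    total <- matrix(tabulate(lin, nx * ny), nx, ny)
    detected <- matrix(tabulate(lin[detected_all], nx * ny), nx, ny)
    p <- detected / total
    p[total == 0] <- NA_real_
    structure(list(x_edges = xe, y_edges = ye, detected = detected,
                   total = total, p = p),
              class = "probability_grid")
  })
}

#' Run the full detection-probability model
#'
#' Runs the configured iteration grid (source level x directivity x
#' replicate seeds) and returns the per-iteration grids with their
#' parameters.
#'
#' @inheritParams run_detection_iteration
#' @param seed Master seed; per-iteration seeds are derived from it.
#' @return List with `grids` (list of `probability_grid`), `params`
#'   (data.frame of per-iteration source level, directivity, seed), `mean`
#'   (the per-bin mean grid across iterations, via [aggregate_probability()]).
#' @export
run_detection_model <- function(config, arrays, bathy, env,
                                tl_model = tl_spherical(), seed = 1) {
  par <- iteration_params(config, seed)
  grids <- lapply(seq_len(nrow(par)), function(k)
    run_detection_iteration(config, arrays, bathy, env, tl_model,
                            seed = par$seed[k],
                            source_level = par$source_level[k],
                            directivity = par$directivity[k]))
  list(grids = grids, params = par, mean = aggregate_probability(grids))
}

#' Aggregate probability grids
#'
#' Per-bin (weighted) mean over a set of grids with identical binning —
#' equal weights for averaging the iterations of one deployment, or
#' deployment durations for combining deployments — with optional
#' max-normalization of the result to [0, 1].
#'
#' @param grids List of `probability_grid` objects.
#' @param weights Optional non-negative weights, one per grid.
#' @param normalize If `TRUE`, divide by the maximum bin value.
#' @return A `probability_grid` with the aggregated `p` (and summed counts).
#' @export
aggregate_probability <- function(grids, weights = NULL, normalize = FALSE) {
  stopifnot(length(grids) >= 1L)
  xe <- grids[[1]]$x_edges; ye <- grids[[1]]$y_edges
  for (g in grids)
    if (!isTRUE(all.equal(g$x_edges, xe)) || !isTRUE(all.equal(g$y_edges, ye)))
      stop("grids have mismatched bin edges")
  weights <- weights %||% rep(1, length(grids))
  stopifnot(length(weights) == length(grids), all(weights >= 0))
  num <- den <- matrix(0, nrow(grids[[1]]$p), ncol(grids[[1]]$p))
  tot <- det <- num
  for (k in seq_along(grids)) {
    pk <- grids[[k]]$p
    ok <- !is.na(pk)
    num[ok] <- num[ok] + weights[k] * pk[ok]
    den[ok] <- den[ok] + weights[k]
    tot <- tot + grids[[k]]$total
    det <- det + grids[[k]]$detected
  }
  p <- num / den
  p[den == 0] <- NA_real_
  if (normalize) {
    m <- max(p, na.rm = TRUE)
    if (m > 0) p <- p / m
  }
  structure(list(x_edges = xe, y_edges = ye, detected = det, total = tot,
                 p = p),
            class = "probability_grid")
}

#' Closed-form on-axis detection radius
#'
#' For the analytic spherical-spreading TL model, solves
#' SL - TL(r) = threshold for the range at which an on-axis (or
#' omnidirectional) click falls to the detection threshold.
#'
#' @param source_level Source level (dB pp).
#' @param threshold_db Detection threshold (dB pp).
#' @param alpha Absorption (dB/m) of the analytic TL model.
#' @return Radius in meters.
#' @export
detection_radius <- function(source_level, threshold_db = 112, alpha = 0.01) {
  f <- function(r) source_level - (20 * log10(r) + alpha * r) - threshold_db
  stats::uniroot(f, c(1, 1e6), tol = 1e-9)$root
}
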