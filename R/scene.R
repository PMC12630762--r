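# Synthetic scene generation: acoustic environment, transmission-loss models,
# dive trajectories, click emission, propagation/detection, and synthetic
# click waveforms. Everything downstream of this module (TDOA measurement,
# localization, behavioral metrics, detection probability) is exercised
# against scenes built here.

#' Acoustic environment
#'
#' @param sound_speed Sound speed in m/s (scalar; must lie in 1400-1600).
#' @param absorption_coeff Seawater absorption in dB/m (>= 0).
#' @param sample_rate Recorder sampling rate in Hz.
#' @return List of class `pam_environment`.
#' @export
make_environment <- function(sound_speed = 1500, absorption_coeff = 0.01,
                             sample_rate = 100e3) {
  if (sound_speed < 1400 || sound_speed > 1600)
    stop("sound_speed must be within [1400, 1600] m/s")
  if (absorption_coeff < 0) stop("absorption_coeff must be >= 0")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(sound_speed = sound_speed,
                 absorption_coeff = absorption_coeff,
                 sample_rate = sample_rate),
            class = "pam_environment")
}

#' Analytic transmission-loss model
#'
#' Spherical spreading plus linear absorption:
#' TL(r) = 20 log10(r / 1 m) + alpha r. The default alpha of 0.01 dB/m is
#' representative of ~40 kHz seawater absorption.
#'
#' @param alpha Absorption coefficient, dB/m.
#' @return A function `tl(range_m, source_depth, receiver_depth)` returning
#'   transmission loss in dB (depth arguments accepted for interface parity
#'   with table-based models; unused here).
#' @export
tl_spherical <- function(alpha = 0.01) {
  force(alpha)
  function(range_m, source_depth = NULL, receiver_depth = NULL) {
    if (any(range_m <= 0)) stop("transmission loss undefined at zero range")
    20 * log10(range_m) + alpha * range_m
  }
}

#' Transmission-loss model from a precomputed table
#'
#' Imports a range (x) by source-depth (optional) TL table, e.g. exported
#' from a ray-tracing run, and returns an interpolating model with the same
#' signature as [tl_spherical()]. The delimited file must have columns
#' `range_m`, `tl_db` and optionally `source_depth_m`; with the depth column
#' present the model interpolates bilinearly in (range, source depth).
#'
#' @param path Delimited text file (comma separated, header row).
#' @return A TL function `tl(range_m, source_depth, receiver_depth)`.
#' @examples
#' tab <- system.file("extdata", "synthetic_tl_table.csv",
#'                    package = "pamtrackr")
#' tl <- tl_from_table(tab)
#' tl(1000, source_depth = 900)
#' @export
tl_from_table <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("range_m", "tl_db") %in% names(tab)))
    stop("TL table needs columns range_m, tl_db")
  if ("source_depth_m" %in% names(tab)) {
    rs <- sort(unique(tab$range_m)); ds <- sort(unique(tab$source_depth_m))
    key <- paste(tab$range_m, tab$source_depth_m)
    g <- expand.grid(range_m = rs, source_depth_m = ds)
    m <- matrix(tab$tl_db[match(paste(g$range_m, g$source_depth_m), key)],
                length(rs), length(ds))
    if (any(is.na(m))) stop("TL table must be a complete range x depth grid")
    function(range_m, source_depth = NULL, receiver_depth = NULL) {
      sd <- if (is.null(source_depth)) rep(ds[1], length(range_m)) else
        rep_len(source_depth, length(range_m))
      r <- pmin(pmax(range_m, rs[1]), rs[length(rs)])
      d <- pmin(pmax(sd, ds[1]), ds[length(ds)])
      ir <- pmin(findInterval(r, rs), length(rs) - 1L)
      id <- pmin(findInterval(d, ds), length(ds) - 1L)
      tr <- (r - rs[ir]) / (rs[ir + 1] - rs[ir])
      td <- (d - ds[id]) / (ds[id + 1] - ds[id])
      (1 - tr) * (1 - td) * m[cbind(ir, id)] +
        tr * (1 - td) * m[cbind(ir + 1L, id)] +
        (1 - tr) * td * m[cbind(ir, id + 1L)] +
        tr * td * m[cbind(ir + 1L, id + 1L)]
    }
  } else {
    o <- order(tab$range_m)
    rs <- tab$range_m[o]; tl <- tab$tl_db[o]
    function(range_m, source_depth = NULL, receiver_depth = NULL)
      stats::approx(rs, tl, xout = range_m, rule = 2)$y
  }
}

#' Dive simulation configuration
#'
#' Defaults emulate deep foraging dives of a beaked whale: a steep, straight
#' descent (default angle -68.8 degrees relative to the sea surface) followed
#' by a correlated random walk confined to an altitude band of 50-200 m above
#' the local seafloor, with echolocation produced only below a start depth of
#' 400 m.
#'
#' @param start_xy Horizontal start position (m, ENU).
#' @param start_time Track start time (s).
#' @param duration_s Total simulated duration (s); deep dives last about an
#'   hour, default 3600.
#' @param dt Trajectory sampling step (s).
#' @param speed Swim speed (m/s).
#' @param descent_angle_deg Descent pitch relative to horizontal, negative
#'   downward.
#' @param heading_deg Initial heading, degrees clockwise from north.
#' @param click_start_depth Depth (m) below which echolocation is on.
#' @param altitude_band Length-2 altitude band (m above seafloor) occupied
#'   during the at-depth phase.
#' @param heading_sd_deg Per-step s.d. of the heading random walk (0 in
#'   noiseless mode).
#' @param angle_sd_deg Per-step s.d. of the descent-angle jitter.
#' @param altitude_sd Per-step s.d. of the vertical jitter at depth (m).
#' @param home_strength Foraging-site fidelity: per-second rate at which the
#'   at-depth heading relaxes toward the bearing to `home_xy` (0 disables).
#'   Keeps the random walk circulating over a foraging patch instead of
#'   drifting away, mirroring the persistent use of specific bathymetric
#'   features seen in tracked dives.
#' @param home_xy Center of the foraging patch; default (`NULL`) is the
#'   position where the at-depth phase begins.
#' @param noiseless If `TRUE`, all stochastic terms are zeroed and the dive
#'   is fully deterministic (no RNG draws).
#' @export
dive_config <- function(start_xy = c(0, 0), start_time = 0, duration_s = 3600,
                        dt = 1, speed = 1.25, descent_angle_deg = -68.8,
                        heading_deg = 0, click_start_depth = 400,
                        altitude_band = c(50, 200), heading_sd_deg = 6,
                        angle_sd_deg = 4, altitude_sd = 0.5,
                        home_strength = 0.03, home_xy = NULL,
                        noiseless = FALSE) {
  stopifnot(duration_s > 0, dt > 0, speed > 0,
            descent_angle_deg < 0, descent_angle_deg >= -90,
            length(altitude_band) == 2L, altitude_band[1] >= 0,
            altitude_band[2] > altitude_band[1])
  as.list(environment())
}

#' Simulate one deep foraging dive
#'
#' The whale starts at the surface, descends on a straight (optionally
#' jittered) path at the configured pitch until it enters the at-depth
#' altitude band, then performs a correlated random walk that holds altitude
#' within the band above the local seafloor. The echolocation flag is true
#' exactly where the whale is below `click_start_depth`. Identical seeds give
#' identical trajectories.
#'
#' @param config A [dive_config()].
#' @param bathy A [bathymetry()] grid covering the dive.
#' @param seed Integer seed for the stochastic terms.
#' @param whale_id Identifier stored in the output.
#' @return A data.frame with columns `whale_id`, `time`, `x`, `y`, `depth`
#'   (m, positive down), `echolocating`, `phase` (simulator truth:
#'   `"descent"` or `"at_depth"`).
#' @export
simulate_dive <- function(config, bathy, seed = 1, whale_id = "w1") {
  cfg <- config
  rng <- range(bathy$x)
  if (cfg$start_xy[1] < rng[1] || cfg$start_xy[1] > rng[2] ||
      cfg$start_xy[2] < min(bathy$y) || cfg$start_xy[2] > max(bathy$y))
    stop("dive start position outside bathymetry extent")
  n <- floor(cfg$duration_s / cfg$dt) + 1L
  sim <- function() {
    x <- y <- depth <- numeric(n)
    phase <- character(n)
    x[1] <- cfg$start_xy[1]; y[1] <- cfg$start_xy[2]; depth[1] <- 0
    heading <- deg2rad(cfg$heading_deg)
    home <- cfg$home_xy
    target_alt <- mean(cfg$altitude_band)
    at_depth <- FALSE
    clipped <- FALSE
    for (k in 2:n) {
      floor_d <- bathy_depth_at(bathy, x[k - 1], y[k - 1])
      alt <- floor_d - depth[k - 1]
      if (!at_depth && alt <= target_alt) at_depth <- TRUE
      if (!at_depth) {
        ang <- deg2rad(cfg$descent_angle_deg +
                         if (cfg$noiseless) 0 else stats::rnorm(1, 0, cfg$angle_sd_deg))
        if (!cfg$noiseless)
          heading <- heading + deg2rad(stats::rnorm(1, 0, cfg$heading_sd_deg))
        dh <- cfg$speed * cos(ang) * cfg$dt
        dv <- -cfg$speed * sin(ang) * cfg$dt      # positive (down) for negative ang
        x[k] <- x[k - 1] + dh * sin(heading)
        y[k] <- y[k - 1] + dh * cos(heading)
        depth[k] <- depth[k - 1] + dv
      } else {
        if (is.null(home)) home <- c(x[k - 1], y[k - 1])
        if (!cfg$noiseless)
          heading <- heading + deg2rad(stats::rnorm(1, 0, cfg$heading_sd_deg))
        if (cfg$home_strength > 0) {
          bearing <- atan2(home[1] - x[k - 1], home[2] - y[k - 1])
          dh_ang <- atan2(sin(bearing - heading), cos(bearing - heading))
          heading <- heading + dh_ang * min(1, cfg$home_strength * cfg$dt)
        }
        # mean-reverting altitude inside the band; horizontal step shrinks
        # so the 3D displacement stays at the configured swim speed
        drift <- 0.05 * (target_alt - alt) * cfg$dt
        dz <- drift + if (cfg$noiseless) 0 else stats::rnorm(1, 0, cfg$altitude_sd)
        step <- cfg$speed * cfg$dt
        dh <- sqrt(max(step^2 - dz^2, (0.1 * step)^2))
        x[k] <- x[k - 1] + dh * sin(heading)
        y[k] <- y[k - 1] + dh * cos(heading)
        depth[k] <- depth[k - 1] - dz       # dz > 0 raises altitude
      }
      # clamp inside grid so lookups stay valid
      x[k] <- min(max(x[k], min(bathy$x)), max(bathy$x))
      y[k] <- min(max(y[k], min(bathy$y)), max(bathy$y))
      fl <- bathy_depth_at(bathy, x[k], y[k])
      if (depth[k] > fl) { depth[k] <- fl; clipped <- TRUE }
      if (at_depth) {
        a <- fl - depth[k]
        a <- min(max(a, cfg$altitude_band[1]), cfg$altitude_band[2])
        depth[k] <- fl - a
      }
      phase[k] <- if (at_depth) "at_depth" else "descent"
    }
    phase[1] <- "descent"
    if (clipped) warning("trajectory clipped at the seafloor")
    data.frame(whale_id = whale_id,
               time = cfg$start_time + (seq_len(n) - 1) * cfg$dt,
               x = x, y = y, depth = depth,
               echolocating = depth >= cfg$click_start_depth,
               phase = phase, stringsAsFactors = FALSE)
  }
  if (cfg$noiseless) sim() else with_seed(seed, sim())
}

#' Emit echolocation clicks along a trajectory
#'
#' Clicks are generated at a regular inter-click interval (optionally
#' jittered) over every maximal interval in which the whale is echolocating;
#' click positions are linearly interpolated and the acoustic axis follows
#' the instantaneous velocity.
#'
#' @param traj A trajectory from [simulate_dive()].
#' @param inter_click_interval Mean ICI in seconds (default 0.4).
#' @param seed RNG seed for jitter and per-click source parameters.
#' @param jitter_frac Uniform ICI jitter as a fraction of the ICI.
#' @param source_level_range Peak-to-peak source level range, dB re 1 uPa
#'   (default 221-223); one value drawn uniformly per click.
#' @param directivity_range Directivity index range, dB (default 23-25).
#' @return data.frame with `whale_id`, `emit_time`, `x`, `y`, `depth`,
#'   `ax`, `ay`, `az` (unit acoustic axis, ENU z up), `source_level`,
#'   `directivity_index`. Zero rows if the whale never echolocates.
#' @export
emit_clicks <- function(traj, inter_click_interval = 0.4, seed = 1,
                        jitter_frac = 0, source_level_range = c(221, 223),
                        directivity_range = c(23, 25)) {
  if (inter_click_interval <= 0) stop("inter_click_interval must be positive")
  runs <- rle(traj$echolocating)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  gen <- function() {
    times <- numeric(0)
    for (r in which(runs$values)) {
      t0 <- traj$time[starts[r]]; t1 <- traj$time[ends[r]]
      if (t1 <= t0) next
      tt <- seq(t0, t1, by = inter_click_interval)
      if (jitter_frac > 0) {
        tt <- tt + stats::runif(length(tt), -jitter_frac, jitter_frac) *
          inter_click_interval
        tt <- sort(tt[tt >= t0 & tt <= t1])
      }
      times <- c(times, tt)
    }
    if (!length(times))
      return(data.frame(whale_id = character(0), emit_time = numeric(0),
                        x = numeric(0), y = numeric(0), depth = numeric(0),
                        ax = numeric(0), ay = numeric(0), az = numeric(0),
                        source_level = numeric(0),
                        directivity_index = numeric(0),
                        stringsAsFactors = FALSE))
    ix <- stats::approx(traj$time, traj$x, xout = times)$y
    iy <- stats::approx(traj$time, traj$y, xout = times)$y
    id <- stats::approx(traj$time, traj$depth, xout = times)$y
    # axis from the trajectory segment containing each click
    seg <- pmin(pmax(findInterval(times, traj$time), 1L), nrow(traj) - 1L)
    vx <- traj$x[seg + 1L] - traj$x[seg]
    vy <- traj$y[seg + 1L] - traj$y[seg]
    vz <- -(traj$depth[seg + 1L] - traj$depth[seg])   # z up
    vn <- sqrt(vx^2 + vy^2 + vz^2)
    vn[vn == 0] <- 1
    sl <- stats::runif(length(times), source_level_range[1], source_level_range[2])
    di <- stats::runif(length(times), directivity_range[1], directivity_range[2])
    data.frame(whale_id = traj$whale_id[1], emit_time = times,
               x = ix, y = iy, depth = id,
               ax = vx / vn, ay = vy / vn, az = vz / vn,
               source_level = sl, directivity_index = di,
               stringsAsFactors = FALSE)
  }
  with_seed(seed, gen())
}

#' Propagate clicks to receiver arrays and apply the detection threshold
#'
#' Received level is RL = SL - TL(r) - off-axis attenuation(theta, DI); a
#' click is kept for an array iff RL is at or above `threshold_db` (default
#' 112 dB pp re 1 uPa, the click-candidate threshold of the localization
#' step). Arrival time is emit time plus slant range over sound speed; the
#' six intra-array TDOAs are computed exactly from the spherical wavefront
#' geometry and then perturbed with i.i.d. Gaussian timing jitter.
#'
#' @param clicks Click table from [emit_clicks()].
#' @param arrays List of [array_geometry()] objects.
#' @param env A [make_environment()].
#' @param tl_model TL function, e.g. [tl_spherical()].
#' @param threshold_db Detection threshold, dB pp re 1 uPa.
#' @param tdoa_jitter_sd TDOA timing jitter s.d. in seconds (default 5e-6).
#' @param seed RNG seed for the jitter.
#' @param beam Beam model passed to [off_axis_attenuation()]'s cap:
#'   `"piston"` (default) or `"omni"` (no off-axis loss).
#' @return data.frame with one row per (click, array) detection: `array_id`,
#'   `whale_id`, `emit_time`, `arrival_time`, `received_level`, `range_m`,
#'   `off_axis_deg`, `tdoa_12` ... `tdoa_34`.
#' @export
propagate_and_detect <- function(clicks, arrays, env, tl_model = tl_spherical(),
                                 threshold_db = 112, tdoa_jitter_sd = 5e-6,
                                 seed = 1, beam = c("piston", "omni")) {
  beam <- match.arg(beam)
  c0 <- env$sound_speed
  out <- lapply(arrays, function(geom) {
    if (!nrow(clicks)) return(NULL)
    src <- cbind(clicks$x, clicks$y, -clicks$depth)
    dvec <- sweep(-src, 2, geom$origin, `+`)       # source -> array
    r <- sqrt(rowSums(dvec^2))
    if (any(r == 0)) stop("click coincides with an array position (zero range)")
    axis <- cbind(clicks$ax, clicks$ay, clicks$az)
    cosang <- rowSums(axis * dvec) / r
    theta <- rad2deg(acos(pmin(pmax(cosang, -1), 1)))
    att <- if (beam == "omni") 0 else
      off_axis_attenuation(theta, clicks$directivity_index)
    rl <- clicks$source_level - tl_model(r, clicks$depth,
                                         -geom$origin[3]) - att
    keep <- rl >= threshold_db
    if (!any(keep)) return(NULL)
    idx <- which(keep)
    td <- t(vapply(idx, function(k)
      spherical_tdoa(src[k, ], geom, c0), numeric(6)))
    data.frame(array_id = geom$array_id,
               whale_id = clicks$whale_id[idx],
               emit_time = clicks$emit_time[idx],
               arrival_time = clicks$emit_time[idx] + r[idx] / c0,
               received_level = rl[idx],
               range_m = r[idx],
               off_axis_deg = theta[idx],
               tdoa_12 = td[, 1], tdoa_13 = td[, 2], tdoa_14 = td[, 3],
               tdoa_23 = td[, 4], tdoa_24 = td[, 5], tdoa_34 = td[, 6],
               stringsAsFactors = FALSE)
  })
  det <- do.call(rbind, out)
  if (is.null(det))
    det <- data.frame(array_id = character(0), whale_id = character(0),
                      emit_time = numeric(0), arrival_time = numeric(0),
                      received_level = numeric(0), range_m = numeric(0),
                      off_axis_deg = numeric(0),
                      tdoa_12 = numeric(0), tdoa_13 = numeric(0),
                      tdoa_14 = numeric(0), tdoa_23 = numeric(0),
                      tdoa_24 = numeric(0), tdoa_34 = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(det) && tdoa_jitter_sd > 0) {
    det <- with_seed(seed, {
      jit <- matrix(stats::rnorm(6L * nrow(det), 0, tdoa_jitter_sd),
                    nrow(det), 6L)
      det[, paste0("tdoa_", c("12", "13", "14", "23", "24", "34"))] <-
        det[, paste0("tdoa_", c("12", "13", "14", "23", "24", "34"))] + jit
      det
    })
  }
  rownames(det) <- NULL
  det
}

#' Synthesize a 4-channel click waveform for one detection
#'
#' A Gaussian-windowed tone (default 36 kHz carrier, 22 us envelope s.d.) is
#' placed on each channel at that channel's true arrival offset implied by
#' the detection's TDOAs, with amplitude matching the received level and
#' optional additive white noise. Used to exercise the waveform
#' cross-correlation TDOA measurement end to end.
#'
#' @param detection One-row detection (list or data.frame row) with fields
#'   `received_level` and `tdoa_12`, `tdoa_13`, `tdoa_14`.
#' @param env A [make_environment()] supplying the sample rate.
#' @param duration_samples Window length in samples.
#' @param center_freq Carrier frequency (Hz).
#' @param envelope_sd Gaussian envelope s.d. (s).
#' @param snr_db Peak signal-to-noise ratio in dB (`Inf` = noiseless).
#' @param seed RNG seed for the noise.
#' @return `duration_samples` x 4 numeric matrix (columns = channels).
#' @export
synthesize_click_waveform <- function(detection, env, duration_samples = 256,
                                      center_freq = 36e3, envelope_sd = 22e-6,
                                      snr_db = Inf, seed = 1) {
  fs <- env$sample_rate
  if (duration_samples / fs < 8 * envelope_sd)
    stop("window shorter than the click envelope")
  # channel arrival times relative to channel 1 (tau_1j = t_1 - t_j)
  rel <- c(0, -detection$tdoa_12, -detection$tdoa_13, -detection$tdoa_14)
  amp <- 10^(detection$received_level / 20) / 2      # pp -> peak amplitude
  tc <- duration_samples / fs / 2
  t <- (seq_len(duration_samples) - 1) / fs
  w <- vapply(rel, function(dtau) {
    tt <- t - (tc + dtau)
    amp * exp(-tt^2 / (2 * envelope_sd^2)) * cos(2 * pi * center_freq * tt)
  }, numeric(duration_samples))
  if (is.finite(snr_db)) {
    w <- with_seed(seed, w + matrix(
      stats::rnorm(length(w), 0, amp / 10^(snr_db / 20)),
      nrow(w), ncol(w)))
  }
  w
}
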