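# End-to-end scenario runner: synthetic scene -> detections -> association
# -> cross-fix localization -> smoothing -> dive metrics -> encounters and
# group behavior -> detection-probability grid, with a machine-readable
# manifest of every seed and parameter.

#' Default scene configuration
#'
#' A coordinated group of `n_whales` whales diving between two tetrahedral
#' arrays 1 km apart over flat 1300 m bathymetry: staggered starts, sub-km
#' spacing, hour-long dives with echolocation at depth.
#'
#' @param n_whales Number of whales (default 3).
#' @param seed Master seed recorded in the config; stage seeds derive from
#'   it.
#' @return Nested configuration list understood by [run_scenario()].
#' @export
default_scene_config <- function(n_whales = 3, seed = 1) {
  offs <- c(0, 210, -190, 320, -350, 140, -260, 430, -80)
  stagger <- c(0, 45, 90, 30, 120, 60, 150, 15, 75)
  list(
    seed = seed,
    bathymetry = list(kind = "flat", params = list(depth = 1300),
                      extent = c(-6000, 6000, -6000, 6000), cell_size = 100),
    environment = list(sound_speed = 1500, absorption_coeff = 0.01,
                       sample_rate = 100e3),
    arrays = list(separation = 1000, edge = 1, altitude = 6),
    whales = lapply(seq_len(n_whales), function(k) list(
      id = sprintf("w%d", k),
      start_xy = c(offs[k], offs[((k %% 9) + 1)] / 2),
      start_time = stagger[k],
      heading_deg = (k - 1) * 120 %% 360)),
    dive = list(duration_s = 3600, dt = 1, speed = 1.25,
                descent_angle_deg = -68.8, click_start_depth = 400,
                altitude_band = c(50, 200)),
    clicks = list(inter_click_interval = 0.4, jitter_frac = 0.05,
                  source_level_range = c(221, 223),
                  directivity_range = c(23, 25)),
    detection = list(threshold_db = 112, tdoa_jitter_sd = 5e-6),
    association = list(bin = 0.02, max_lag = 2, threshold = 0.5),
    smoothing = list(process_noise = 0.1, window = 5),
    metrics = list(phase_threshold_m = 200, encounter_gap_min = 30),
    groups = list(distance_cutoff = 1000, overlap_minutes = 10,
                  density_bin = 10),
    detprob = list(enabled = TRUE, n_whales = 10000, n_sl = 3, n_di = 3,
                   n_replicates = 15)
  )
}

#' Read a scenario configuration from YAML or JSON
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

validate_scene_config <- function(config) {
  req <- c("bathymetry", "environment", "arrays", "whales", "dive",
           "clicks", "detection")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("configuration error: missing field(s) ", paste(miss, collapse = ", "))
  b <- config$bathymetry
  if (!is.null(b$path) && !file.exists(b$path))
    stop("configuration error: bathymetry$path does not exist: ", b$path)
  if (is.null(b$path) && is.null(b$kind))
    stop("configuration error: bathymetry needs either 'path' or 'kind'")
  invisible(config)
}

# build the two arrays sitting `altitude` m above the seafloor, `separation`
# m apart east-west, centered on the frame origin
scene_arrays <- function(config, bathy) {
  sep <- config$arrays$separation %||% 1000
  alt <- config$arrays$altitude %||% 6
  edge <- config$arrays$edge %||% 1
  xs <- c(-sep / 2, sep / 2)
  lapply(1:2, function(k) {
    d <- bathy_depth_at(bathy, xs[k], 0)
    tetrahedral_array(c(xs[k], 0, -(d - alt)), edge = edge,
                      array_id = c("A", "B")[k],
                      altitude_above_seafloor = alt)
  })
}

#' Localize associated detections into smoothed tracks
#'
#' Per-array detections are grouped into click trains, trains are associated
#' across arrays by click-train cross-correlation, clicks of associated
#' trains are matched by arrival time with a running lag update, and every
#' matched click is localized by a two-ray cross-fix with jackknife 95%
#' confidence intervals, then Kalman + moving-average smoothed.
#'
#' @param detections Detection data.frame covering both arrays (as from
#'   [propagate_and_detect()]), with a `whale_id` (or `truth_whale_id`)
#'   column standing in for the manual per-array track sorting.
#' @param geom_a,geom_b The two [array_geometry()] objects.
#' @param env A [make_environment()].
#' @param association List of association parameters (`bin`, `max_lag`,
#'   `threshold`).
#' @param smoothing List of smoothing parameters (`process_noise`,
#'   `window`).
#' @param match_tol Residual arrival-time tolerance when matching clicks
#'   within an associated train pair (s).
#' @return Named list of smoothed track data.frames (one per associated
#'   pair), each with `whale_id`, `time`, `x`, `y`, `depth`, `ci95_x/y/z`,
#'   smoothed columns, and `n_jackknife`.
#' @export
localize_detections <- function(detections, geom_a, geom_b, env,
                                association = list(), smoothing = list(),
                                match_tol = 0.2) {
  idcol <- if ("whale_id" %in% names(detections)) "whale_id" else "truth_whale_id"
  tcol <- if ("arrival_time" %in% names(detections)) "arrival_time" else "arrival_time_s"
  da <- detections[detections$array_id == geom_a$array_id, , drop = FALSE]
  db <- detections[detections$array_id == geom_b$array_id, , drop = FALSE]
  if (!nrow(da) || !nrow(db)) return(list())
  trains_a <- split(da[[tcol]], da[[idcol]])
  trains_b <- split(db[[tcol]], db[[idcol]])
  pair <- associate_click_trains(trains_a, trains_b,
                                 max_lag = association$max_lag %||% 2,
                                 threshold = association$threshold %||% 0.5,
                                 bin = association$bin %||% 0.02,
                                 segment_s = association$segment_s %||% 30)
  tdcols <- paste0("tdoa_", c("12", "13", "14", "23", "24", "34"))
  tracks <- list()
  for (k in seq_len(nrow(pair))) {
    ia <- which(da[[idcol]] == pair$train_a[k])
    ib <- which(db[[idcol]] == pair$train_b[k])
    ta <- da[[tcol]][ia]; tb <- db[[tcol]][ib]
    oa <- order(ta); ia <- ia[oa]; ta <- ta[oa]
    ob <- order(tb); ib <- ib[ob]; tb <- tb[ob]
    # match clicks outward from the association anchor with a running lag
    # update (the inter-array lag drifts as the whale moves)
    anchor <- pair$anchor_s[k]
    if (is.na(anchor)) anchor <- ta[1]
    k0 <- which.min(abs(ta - anchor))
    lag_at <- rep(NA_real_, length(ia))
    for (dir in c(1L, -1L)) {
      lag <- pair$lag_s[k]
      idx <- if (dir > 0) k0:length(ia) else rev(seq_len(k0 - 1L))
      for (m in idx) {
        jb <- nearest_index(tb, ta[m] + lag)
        if (abs(tb[jb] - (ta[m] + lag)) > match_tol) next
        lag <- tb[jb] - ta[m]
        lag_at[m] <- lag
      }
    }
    pts <- vector("list", length(ia))
    for (m in seq_along(ia)) {
      if (is.na(lag_at[m])) next
      jb <- nearest_index(tb, ta[m] + lag_at[m])
      fix <- tryCatch(
        jackknife_ci(as.numeric(da[ia[m], tdcols]),
                     as.numeric(db[ib[jb], tdcols]),
                     geom_a, geom_b, sound_speed = env$sound_speed),
        error = function(e) NULL)
      if (is.null(fix)) next
      pts[[m]] <- data.frame(time = ta[m],
                             x = fix$position[1], y = fix$position[2],
                             depth = -fix$position[3],
                             ci95_x = fix$ci95[1], ci95_y = fix$ci95[2],
                             ci95_z = fix$ci95[3],
                             n_jackknife = fix$n_jackknife)
    }
    tr <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
    if (is.null(tr) || nrow(tr) < 3L) next
    tr <- tr[!duplicated(tr$time), , drop = FALSE]
    tr <- tr[order(tr$time), , drop = FALSE]
    tr$whale_id <- pair$train_a[k]
    tr <- smooth_track(tr,
                       process_noise = smoothing$process_noise %||% 0.1,
                       window = smoothing$window %||% 5)
    tracks[[pair$train_a[k]]] <- tr
  }
  tracks
}

#' Run a full synthetic scenario end to end
#'
#' Chains scene generation, propagation/detection, cross-array association,
#' localization and smoothing, dive metrics, encounter segmentation and
#' group behavior, and the detection-probability model; writes all outputs
#' and a manifest to `out_dir`. Deterministic for a fixed config seed.
#'
#' @param config Configuration list ([default_scene_config()] or
#'   [read_scene_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list with the in-memory results (`bathy`, `arrays`,
#'   `detections`, `tracks`, `metrics`, `encounters`, `group_size`,
#'   `subgroups`, `density`, `detprob`, `manifest`).
#' @export
run_scenario <- function(config, out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  validate_scene_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  seeds <- derive_seeds(config$seed %||% 1, 6)

  bathy <- stage("bathymetry", {
    b <- config$bathymetry
    if (!is.null(b$path)) read_esri_ascii(b$path)
    else generate_bathymetry(b$kind, b$params %||% list(),
                             extent = b$extent %||% c(-6000, 6000, -6000, 6000),
                             cell_size = b$cell_size %||% 100)
  })
  env <- stage("environment", do.call(make_environment, config$environment))
  arrays <- stage("arrays", scene_arrays(config, bathy))

  scene <- stage("scene", {
    wseeds <- derive_seeds(seeds[1], length(config$whales))
    trajs <- list(); clicks <- list()
    for (k in seq_along(config$whales)) {
      w <- config$whales[[k]]
      cfg <- do.call(dive_config, c(list(start_xy = w$start_xy,
                                         start_time = w$start_time %||% 0,
                                         heading_deg = w$heading_deg %||% 0),
                                    config$dive))
      trajs[[w$id]] <- simulate_dive(cfg, bathy, seed = wseeds[k],
                                     whale_id = w$id)
      clicks[[w$id]] <- do.call(emit_clicks,
        c(list(traj = trajs[[w$id]], seed = wseeds[k] + 1L), config$clicks))
    }
    list(trajs = trajs, clicks = do.call(rbind, clicks))
  })

  detections <- stage("detection",
    propagate_and_detect(scene$clicks, arrays, env,
                         tl_model = tl_spherical(env$absorption_coeff),
                         threshold_db = config$detection$threshold_db %||% 112,
                         tdoa_jitter_sd = config$detection$tdoa_jitter_sd %||% 5e-6,
                         seed = seeds[2]))

  tracks <- stage("localization",
    localize_detections(detections, arrays[[1]], arrays[[2]], env,
                        association = config$association %||% list(),
                        smoothing = config$smoothing %||% list()))

  metrics <- stage("metrics", {
    if (length(tracks))
      track_metrics(tracks, bathy,
                    threshold_m = config$metrics$phase_threshold_m %||% 200,
                    min_step_m = config$metrics$angle_min_step_m %||% 20)
    else NULL
  })

  grp <- stage("groups", {
    enc <- segment_encounters(detections$arrival_time,
                              gap_minutes = config$metrics$encounter_gap_min %||% 30)
    ids_a <- unique(detections$whale_id[detections$array_id == arrays[[1]]$array_id])
    ids_b <- unique(detections$whale_id[detections$array_id == arrays[[2]]$array_id])
    pairings <- if (length(tracks))
      data.frame(train_a = names(tracks), train_b = names(tracks)) else NULL
    gs <- group_size(ids_a, ids_b, pairings)
    sub <- if (length(tracks) >= 2)
      find_subgroups(tracks,
                     distance_cutoff = config$groups$distance_cutoff %||% 1000,
                     overlap_minutes = config$groups$overlap_minutes %||% 10)
      else NULL
    dens <- if (length(tracks))
      track_density(tracks, bin_size = config$groups$density_bin %||% 10)
      else NULL
    list(encounters = enc, group_size = gs, subgroups = sub, density = dens)
  })

  dp <- stage("detprob", {
    d <- config$detprob %||% list(enabled = FALSE)
    if (!isTRUE(d$enabled)) NULL
    else {
      cfg <- detprob_config(n_whales = d$n_whales %||% 10000,
                            n_sl = d$n_sl %||% 3, n_di = d$n_di %||% 3,
                            n_replicates = d$n_replicates %||% 15,
                            threshold_db = config$detection$threshold_db %||% 112)
      run_detection_model(cfg, arrays, bathy, env,
                          tl_model = tl_spherical(env$absorption_coeff),
                          seed = seeds[3])
    }
  })

  stage("outputs", {
    write_detections(detections, file.path(out_dir, "detections.csv"))
    if (length(tracks)) {
      allt <- do.call(rbind, lapply(tracks, function(tr) tr))
      write_tracks(allt, file.path(out_dir, "tracks.csv"))
    }
    if (!is.null(metrics))
      utils::write.csv(metrics, file.path(out_dir, "track_metrics.csv"),
                       row.names = FALSE)
    utils::write.csv(grp$encounters, file.path(out_dir, "encounters.csv"),
                     row.names = FALSE)
    summ <- data.frame(encounter_id = 1L, group_size = grp$group_size,
                       n_subgroups = if (is.null(grp$subgroups)) NA_integer_
                                     else grp$subgroups$n_subgroups,
                       mean_subgroup_size = if (is.null(grp$subgroups)) NA_real_
                                            else grp$subgroups$mean_size)
    utils::write.csv(summ, file.path(out_dir, "encounter_summary.csv"),
                     row.names = FALSE)
    if (!is.null(grp$density))
      write_esri_ascii(list(x = grp$density$x_edges[-1] -
                              diff(grp$density$x_edges) / 2,
                            y = grp$density$y_edges[-1] -
                              diff(grp$density$y_edges) / 2,
                            depth = grp$density$counts,
                            cell_size = diff(grp$density$x_edges)[1]),
                       file.path(out_dir, "track_density.asc"))
    if (!is.null(dp)) {
      g <- dp$mean
      xc <- g$x_edges[-1] - diff(g$x_edges) / 2
      yc <- g$y_edges[-1] - diff(g$y_edges) / 2
      long <- expand.grid(x_bin = xc, y_bin = yc)
      long$p <- as.vector(g$p)
      utils::write.csv(long, file.path(out_dir, "detection_probability.csv"),
                       row.names = FALSE)
    }
    manifest <- list(seed = config$seed, stage_seeds = seeds,
                     config = config,
                     outputs = setdiff(list.files(out_dir), "manifest.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  invisible(list(bathy = bathy, arrays = arrays, env = env,
                 trajectories = scene$trajs, clicks = scene$clicks,
                 detections = detections, tracks = tracks,
                 metrics = metrics, encounters = grp$encounters,
                 group_size = grp$group_size, subgroups = grp$subgroups,
                 density = grp$density, detprob = dp))
}
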