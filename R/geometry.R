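# Array geometry, TDOA conventions, DOA inversion, cross-fix localization,
# jackknife confidence intervals, and receiver self-calibration.
#
# Conventions used throughout:
#   * Coordinates are local Cartesian ENU in meters (x east, y north, z UP);
#     underwater points have negative z. User-facing tables express the
#     vertical axis as depth in meters positive-down; conversion happens at
#     table boundaries, never inside the geometry code.
#   * Hydrophone pairs are enumerated in the fixed order
#     (1,2), (1,3), (1,4), (2,3), (2,4), (3,4).
#   * TDOA sign: tau_ij = t_i - t_j = -(p_i - p_j) . u / c under the
#     plane-wave assumption, with u the unit vector pointing from the array
#     toward the source.

#' Hydrophone pair order
#'
#' The fixed enumeration of the six hydrophone pairs of a 4-phone array used
#' for every TDOA vector in the package: (1,2), (1,3), (1,4), (2,3), (2,4),
#' (3,4).
#'
#' @return A 6 x 2 integer matrix of phone indices.
#' @export
tdoa_pairs <- function() {
  cbind(i = c(1L, 1L, 1L, 2L, 2L, 3L),
        j = c(2L, 3L, 4L, 3L, 4L, 4L))
}

#' Construct an array geometry
#'
#' @param origin Numeric length-3 ENU position (m, z up) of the array
#'   reference point (the phone centroid).
#' @param phone_offsets 4 x 3 numeric matrix of phone positions relative to
#'   `origin` (m).
#' @param array_id Identifier for the array.
#' @param altitude_above_seafloor Height of the array reference point above
#'   the local seafloor (m); informational.
#' @return An object of class `array_geometry` with elements `origin`,
#'   `phone_offsets`, `phones` (absolute positions), `array_id`.
#' @export
array_geometry <- function(origin, phone_offsets, array_id = "A",
                           altitude_above_seafloor = 6) {
  origin <- vec3(origin)
  phone_offsets <- as.matrix(phone_offsets)
  if (!all(dim(phone_offsets) == c(4L, 3L)))
    stop("phone_offsets must be a 4 x 3 matrix (exactly 4 phones)")
  # non-coplanarity: the three edge vectors from phone 1 must span 3D
  edges <- sweep(phone_offsets[-1, , drop = FALSE], 2, phone_offsets[1, ])
  if (abs(det(edges)) < 1e-12)
    stop("phone offsets are coplanar; DOA inversion would be rank-deficient")
  structure(list(origin = origin,
                 phone_offsets = phone_offsets,
                 phones = sweep(phone_offsets, 2, origin, `+`),
                 array_id = array_id,
                 altitude_above_seafloor = altitude_above_seafloor),
            class = "array_geometry")
}

#' Regular tetrahedral array with a horizontal base
#'
#' Three phones form a horizontal equilateral triangle and the fourth sits
#' above their centroid; all six edges have length `edge` (default 1 m, the
#' deployed aperture). The phone centroid is at `origin`.
#'
#' @inheritParams array_geometry
#' @param edge Edge length in meters.
#' @export
tetrahedral_array <- function(origin, edge = 1, array_id = "A",
                              altitude_above_seafloor = 6) {
  stopifnot(edge > 0)
  r <- edge / sqrt(3)          # base circumradius
  h <- edge * sqrt(2 / 3)      # apex height above base
  base_z <- -h / 4             # centroid at z = 0
  ang <- c(90, 210, 330) * pi / 180
  offs <- rbind(cbind(r * cos(ang), r * sin(ang), base_z),
                c(0, 0, 3 * h / 4))
  array_geometry(origin, offs, array_id = array_id,
                 altitude_above_seafloor = altitude_above_seafloor)
}

#' Forward-model plane-wave TDOAs
#'
#' Noise-free TDOAs for a plane wave arriving from unit direction `u`
#' (array toward source): tau_ij = -(p_i - p_j) . u / c.
#'
#' @param u Unit vector from the array toward the source (ENU, z up).
#' @param geometry An [array_geometry()].
#' @param sound_speed Sound speed in m/s.
#' @return Numeric length-6 TDOA vector (s) in [tdoa_pairs()] order.
#' @export
forward_tdoa <- function(u, geometry, sound_speed = 1500) {
  u <- unit3(vec3(u))
  p <- tdoa_pairs()
  b <- geometry$phone_offsets[p[, 1], ] - geometry$phone_offsets[p[, 2], ]
  as.numeric(-(b %*% u) / sound_speed)
}

#' Exact spherical-wave TDOAs from a source position
#'
#' @param source ENU position (z up) of the source.
#' @inheritParams forward_tdoa
#' @export
spherical_tdoa <- function(source, geometry, sound_speed = 1500) {
  source <- vec3(source)
  rng <- sqrt(rowSums(sweep(geometry$phones, 2, source)^2))
  p <- tdoa_pairs()
  (rng[p[, 1]] - rng[p[, 2]]) / sound_speed
}

#' Estimate direction of arrival from a TDOA set
#'
#' Least-squares plane-wave inversion. With baseline matrix B whose rows are
#' the phone-pair offset vectors p_i - p_j, solves B u = -c tau in the
#' least-squares sense and normalizes the solution.
#'
#' @param tdoas Length-6 TDOA vector (s) in [tdoa_pairs()] order; entries for
#'   invalid pairs may be `NA`.
#' @param geometry An [array_geometry()].
#' @param sound_speed Sound speed (m/s).
#' @param valid Logical length-6 mask of usable pairs (default: non-NA).
#' @return List with `unit_vector` (ENU, z up), `azimuth` (deg clockwise from
#'   north, [0, 360)), `elevation` (deg above horizontal, [-90, 90]),
#'   `residual_rms` (s), `n_pairs`.
#' @export
estimate_doa <- function(tdoas, geometry, sound_speed = 1500, valid = NULL) {
  tdoas <- as.numeric(tdoas)
  stopifnot(length(tdoas) == 6L)
  if (is.null(valid)) valid <- !is.na(tdoas)
  valid <- valid & !is.na(tdoas)
  if (sum(valid) < 3L)
    stop("need at least 3 valid TDOA pairs to invert a direction")
  p <- tdoa_pairs()[valid, , drop = FALSE]
  B <- geometry$phone_offsets[p[, 1], , drop = FALSE] -
       geometry$phone_offsets[p[, 2], , drop = FALSE]
  sv <- svd(B)$d
  if (sv[3] < 1e-10 * sv[1])
    stop("selected phone pairs are rank-deficient (coplanar geometry)")
  u <- unname(qr.solve(B, -sound_speed * tdoas[valid]))
  nu <- norm3(u)
  if (nu == 0) stop("degenerate TDOA set: zero direction solution")
  u <- u / nu
  res <- as.numeric(B %*% u) / sound_speed + tdoas[valid]
  list(unit_vector = u,
       azimuth = (rad2deg(atan2(u[1], u[2])) + 360) %% 360,
       elevation = rad2deg(asin(max(-1, min(1, u[3])))),
       residual_rms = sqrt(mean(res^2)),
       n_pairs = sum(valid))
}

#' Cross-fix two DOA rays
#'
#' Position estimate at the midpoint of the mutual perpendicular segment
#' between the two bearing rays. Both ray parameters must be non-negative
#' (the source must lie in front of both arrays).
#'
#' @param origin_a,origin_b Ray origins (array reference points, ENU z up).
#' @param u_a,u_b Unit direction vectors of the rays.
#' @param min_angle_deg Smallest permissible angle between the rays.
#' @return List with `position` (midpoint), `miss_distance` (length of the
#'   mutual perpendicular, m), `s_a`, `s_b` (ray parameters, m).
#' @export
cross_fix <- function(origin_a, u_a, origin_b, u_b, min_angle_deg = 0.05) {
  a <- unit3(vec3(u_a)); b <- unit3(vec3(u_b))
  A <- vec3(origin_a);  B <- vec3(origin_b)
  d <- sum(a * b)
  sin2 <- 1 - d^2
  if (sin2 < sin(deg2rad(min_angle_deg))^2)
    stop(sprintf("DOA rays are within %.3f deg of (anti)parallel; no stable cross-fix",
                 min_angle_deg))
  w0 <- A - B
  s_a <- (-sum(w0 * a) + d * sum(w0 * b)) / sin2
  s_b <- sum(w0 * b) + s_a * d
  if (s_a < 0 || s_b < 0)
    stop("cross-fix lies behind an array (negative ray parameter)")
  P <- A + s_a * a
  Q <- B + s_b * b
  list(position = (P + Q) / 2,
       miss_distance = norm3(P - Q),
       s_a = s_a, s_b = s_b)
}

#' Jackknife 95% confidence interval for a cross-fixed position
#'
#' Re-localizes the source six times, each time dropping the same TDOA pair
#' index from both arrays, and converts the jackknife variance of the six
#' re-localizations to per-axis Student-t confidence half-widths:
#' var_jk = (n-1)/n * sum_k (theta_k - theta_bar)^2 with n = 6, and
#' half-width = t(1 - (1-conf)/2, df = n - 1) * sqrt(var_jk).
#'
#' @param tdoas_a,tdoas_b Length-6 TDOA vectors for the two arrays.
#' @param geometry_a,geometry_b The two [array_geometry()] objects.
#' @param sound_speed Sound speed (m/s).
#' @param confidence Confidence level (default 0.95).
#' @param drop One of `"both"` (default: drop pair k from both arrays
#'   simultaneously, 6 subsets) or `"single"` (drop pair k from one array at
#'   a time, 12 subsets).
#' @return List with `position` (full 6-pair estimate, ENU z up), `ci95`
#'   (per-axis half-widths, m), `n_jackknife`, `replicates` (n x 3 matrix).
#' @export
jackknife_ci <- function(tdoas_a, tdoas_b, geometry_a, geometry_b,
                         sound_speed = 1500, confidence = 0.95,
                         drop = c("both", "single")) {
  drop <- match.arg(drop)
  fix_for <- function(va, vb) {
    da <- estimate_doa(tdoas_a, geometry_a, sound_speed, valid = va)
    db <- estimate_doa(tdoas_b, geometry_b, sound_speed, valid = vb)
    cross_fix(geometry_a$origin, da$unit_vector,
              geometry_b$origin, db$unit_vector)$position
  }
  full <- fix_for(rep(TRUE, 6), rep(TRUE, 6))
  subsets <- if (drop == "both") {
    lapply(1:6, function(k) {
      v <- rep(TRUE, 6); v[k] <- FALSE
      list(a = v, b = v)
    })
  } else {
    c(lapply(1:6, function(k) {
        v <- rep(TRUE, 6); v[k] <- FALSE
        list(a = v, b = rep(TRUE, 6))
      }),
      lapply(1:6, function(k) {
        v <- rep(TRUE, 6); v[k] <- FALSE
        list(a = rep(TRUE, 6), b = v)
      }))
  }
  reps <- t(vapply(subsets, function(s) fix_for(s$a, s$b), numeric(3)))
  n <- nrow(reps)
  ctr <- colMeans(reps)
  var_jk <- (n - 1) / n * colSums(sweep(reps, 2, ctr)^2)
  tq <- stats::qt(1 - (1 - confidence) / 2, df = n - 1)
  list(position = full,
       ci95 = tq * sqrt(var_jk),
       n_jackknife = n,
       replicates = reps)
}

#' Self-calibrate receiver positions from ship-noise TDOAs
#'
#' Nonlinear least squares for the four phone positions of one array from
#' intra-array TDOAs of ship engine noise recorded at known (GPS) ship
#' positions: minimizes sum over ship points of (measured - modeled)^2 TDOAs,
#' with modeled tau_ij = (|s - p_i| - |s - p_j|)/c.
#'
#' @param ship_positions n x 3 matrix of known ship positions (ENU, z up;
#'   surface points have z near 0).
#' @param measured_tdoas n x 6 matrix of measured TDOAs (s), pair order
#'   [tdoa_pairs()].
#' @param initial_guess 4 x 3 matrix of starting phone positions.
#' @param sound_speed Sound speed (m/s).
#' @param max_condition Condition-number threshold on the Jacobian at the
#'   initial guess beyond which the geometry is declared ill-conditioned.
#'   Intra-array TDOAs constrain the array centroid only weakly, so even
#'   healthy geometries are fairly ill-conditioned; the default flags only
#'   genuinely degenerate (e.g. collinear) ship tracks.
#' @param submerged If `TRUE` (default), constrain all phone z coordinates
#'   to be at or below the sea surface, which removes the mirror solution
#'   reflected through the plane of the (surface) ship positions.
#' @return List with `positions` (4 x 3), `rms_residual` (s), `displacement`
#'   (m moved from the initial guess, per phone), `info` (solver status).
#' @export
calibrate_receivers <- function(ship_positions, measured_tdoas, initial_guess,
                                sound_speed = 1500, max_condition = 1e10,
                                submerged = TRUE) {
  ship_positions <- as.matrix(ship_positions)
  measured_tdoas <- as.matrix(measured_tdoas)
  initial_guess <- as.matrix(initial_guess)
  stopifnot(ncol(ship_positions) == 3L, ncol(measured_tdoas) == 6L,
            nrow(ship_positions) == nrow(measured_tdoas),
            all(dim(initial_guess) == c(4L, 3L)))
  if (nrow(ship_positions) < 4L)
    stop("need at least 4 ship positions for receiver calibration")
  p <- tdoa_pairs()
  model <- function(par) {
    phones <- matrix(par, 4, 3)
    rng <- apply(phones, 1, function(ph)
      sqrt(colSums((t(ship_positions) - ph)^2)))   # n x 4
    (rng[, p[, 1]] - rng[, p[, 2]]) / sound_speed  # n x 6
  }
  resid_fn <- function(par) as.numeric(measured_tdoas - model(par))
  par0 <- as.numeric(initial_guess)
  # conditioning diagnostic: numeric Jacobian at the initial guess
  J <- vapply(seq_along(par0), function(k) {
    h <- 1e-4
    pp <- par0; pp[k] <- pp[k] + h
    pm <- par0; pm[k] <- pm[k] - h
    (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }, numeric(length(measured_tdoas)))
  sv <- svd(J)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > max_condition)
    stop(sprintf(paste0("ship-track geometry is ill-conditioned for receiver ",
                        "inversion (condition number %.3g); spread the ship ",
                        "positions around the array"),
                 if (sv[length(sv)] > 0) sv[1] / sv[length(sv)] else Inf))
  upper <- rep(Inf, length(par0))
  if (submerged) upper[9:12] <- 0          # z components (column-major 4 x 3)
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  if (fit$info %in% c(0, 9))
    stop("receiver calibration failed to converge: ", fit$message)
  phones <- matrix(fit$par, 4, 3)
  list(positions = phones,
       rms_residual = sqrt(mean(resid_fn(fit$par)^2)),
       displacement = sqrt(rowSums((phones - initial_guess)^2)),
       info = fit$message)
}
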