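# encounter segmentation, altitude, dive phases, descent angle, swim speeds

test_that("encounters split exactly at gaps strictly over 30 minutes", {
  enc <- segment_encounters(c(0, 20, 55, 90) * 60)
  expect_equal(nrow(enc), 3L)
  expect_equal(enc$n_detections, c(2L, 1L, 1L))
  expect_equal(attr(enc, "assignment"), c(1L, 1L, 2L, 3L))
  # a gap of exactly 30 min does not split (strict >)
  enc2 <- segment_encounters(c(0, 1800, 3600))
  expect_equal(nrow(enc2), 1L)
  enc3 <- segment_encounters(c(0, 1800.001, 3600))
  expect_equal(nrow(enc3), 2L)                  # first gap just over 30 min
  enc4 <- segment_encounters(c(0, 1801, 3500))
  expect_equal(nrow(enc4), 2L)
  # base cases
  expect_equal(nrow(segment_encounters(42)), 1L)
  expect_equal(nrow(segment_encounters(numeric(0))), 0L)
})

test_that("encounter segmentation is idempotent and order-invariant", {
  set.seed(8)
  for (k in 1:20) {
    t <- cumsum(stats::rexp(50, 1 / 400))
    sh <- sample(t)
    e1 <- segment_encounters(t)
    e2 <- segment_encounters(sh)
    expect_equal(e1, e2, ignore_attr = TRUE)
    expect_equal(attr(e1, "assignment")[order(t)],
                 attr(e2, "assignment")[order(sh)])
  }
})

test_that("altitude above the seafloor is depth difference at the nearest node", {
  b <- flat_bathy(1300)
  tr <- data.frame(x = c(0, 10), y = c(0, -20), depth = c(1150, 1300))
  expect_equal(altitude_above_seafloor(tr, b), c(150, 0))
  # sloped fixture against a hand-picked nearest node
  bs <- generate_bathymetry("slope", list(depth = 1250, gradient_x = 0.1),
                            c(-500, 500, -500, 500), 100)
  tr2 <- data.frame(x = 149, y = 0, depth = 1000)   # nearest node x = 100
  expect_equal(altitude_above_seafloor(tr2, bs), 1250 + 0.1 * 100 - 1000)
})

test_that("phase classification switches one-way at 200 m inclusive", {
  b <- flat_bathy(1300)
  alts <- c(600, 350, 180, 250, 90)
  tr <- data.frame(x = 0, y = 0, depth = 1300 - alts)
  expect_equal(classify_phases(tr, b),
               c("initial_descent", "initial_descent", "at_depth",
                 "at_depth", "at_depth"))
  # exactly 200 m counts as at depth ("within 200 m")
  tr200 <- data.frame(x = 0, y = 0, depth = c(500, 1100, 900))
  expect_equal(classify_phases(tr200, b),
               c("initial_descent", "at_depth", "at_depth"))
  # never within threshold: all initial descent
  trhi <- data.frame(x = 0, y = 0, depth = c(100, 500, 900))
  expect_equal(unique(classify_phases(trhi, b)), "initial_descent")
})

test_that("phase labels are monotone for simulated dives", {
  b <- flat_bathy()
  for (s in 1:5) {
    tr <- simulate_dive(dive_config(duration_s = 1200), b, seed = s)
    ph <- classify_phases(tr, b)
    expect_true(all(diff(ph == "at_depth") >= 0))
  }
})

test_that("descent angle recovers constant and mixture samples", {
  # straight -70 deg descent
  t <- 0:100
  tr <- data.frame(time = t, x = t * cos(70 * pi / 180), y = 0,
                   depth = t * sin(70 * pi / 180))
  a <- descent_angle(tr)
  expect_equal(a$angle_deg, -70, tolerance = 0.1)
  expect_equal(a$sd_deg, 0, tolerance = 1e-9)
  # bimodal 80/20 mixture peaks at the dominant mode
  set.seed(12)
  ang <- c(stats::rnorm(400, -70, 2), stats::rnorm(100, -20, 2))
  dh <- cos(ang * pi / 180); dz <- -sin(ang * pi / 180)  # depth increment
  tr2 <- data.frame(time = seq_along(ang), x = cumsum(c(0, dh))[-1],
                    y = 0, depth = cumsum(c(0, dz))[-1])
  tr2 <- rbind(data.frame(time = 0, x = 0, y = 0, depth = 0), tr2)
  a2 <- descent_angle(tr2)
  expect_lt(abs(a2$angle_deg + 70), 2)
})

test_that("simulator descent angles are recovered from noisy dives", {
  b <- flat_bathy()
  est <- vapply(1:20, function(s) {
    tr <- simulate_dive(dive_config(), b, seed = s)
    ph <- classify_phases(tr, b)
    descent_angle(tr, ph)$angle_deg
  }, numeric(1))
  expect_true(all(abs(est + 68.8) < 2))
})

test_that("descent angle tolerates position noise via smoothing and step aggregation", {
  b <- flat_bathy()
  est <- vapply(1:20, function(s) {
    tr <- simulate_dive(dive_config(), b, seed = s)
    set.seed(s + 1000)
    tr$x <- tr$x + stats::rnorm(nrow(tr), 0, 10)
    tr$y <- tr$y + stats::rnorm(nrow(tr), 0, 10)
    tr$depth <- tr$depth + stats::rnorm(nrow(tr), 0, 10)
    sm <- smooth_track(tr, ci_floor = 10)
    ph <- classify_phases(tr, b)
    descent_angle(sm, ph, min_step_m = 50)$angle_deg
  }, numeric(1))
  expect_true(all(abs(est + 68.8) < 5))
  expect_lt(abs(mean(est) + 68.8), 2)
})

test_that("swim speeds honor the 5/10-minute phase duration filters", {
  # constant 1.5 m/s for 20 min at depth
  t <- 0:1200
  tr <- data.frame(time = t, x = 1.5 * t, y = 0, depth = 1200)
  ph <- rep("at_depth", length(t))
  sp <- swim_speeds(tr, ph)
  expect_equal(sp$at_depth_mps, 1.5, tolerance = 1e-12)
  expect_true(is.na(sp$descent_mps))
  # a 4-minute descent is excluded (< 5 min), a 6-minute one is kept
  t2 <- 0:600
  tr2 <- data.frame(time = t2, x = t2, y = 0, depth = t2)
  ph4 <- ifelse(t2 <= 240, "initial_descent", "at_depth")
  expect_true(is.na(swim_speeds(tr2, ph4)$descent_mps))
  ph6 <- ifelse(t2 <= 360, "initial_descent", "at_depth")
  expect_equal(swim_speeds(tr2, ph6)$descent_mps, sqrt(2), tolerance = 1e-12)
  # boundary: exactly 5 minutes of descent is included
  ph5 <- ifelse(t2 <= 300, "initial_descent", "at_depth")
  expect_false(is.na(swim_speeds(tr2, ph5)$descent_mps))
})

test_that("swim speed medians match a brute-force recomputation on a zig-zag", {
  set.seed(20)
  n <- 800
  tr <- data.frame(time = cumsum(stats::runif(n, 0.5, 1.5)),
                   x = cumsum(stats::rnorm(n)), y = cumsum(stats::rnorm(n)),
                   depth = 1100 + cumsum(stats::rnorm(n, 0, 0.5)))
  ph <- rep("at_depth", n)
  sp <- swim_speeds(tr, ph)
  brute <- stats::median(sapply(2:n, function(k)
    sqrt(sum((tr[k, c("x", "y", "depth")] - tr[k - 1, c("x", "y", "depth")])^2)) /
      (tr$time[k] - tr$time[k - 1])))
  expect_equal(sp$at_depth_mps, brute, tolerance = 1e-12)
})

test_that("swim speeds are invariant to rigid translation and rotation about the vertical axis", {
  set.seed(21)
  n <- 200
  tr <- data.frame(time = 1:n, x = cumsum(stats::rnorm(n)),
                   y = cumsum(stats::rnorm(n)),
                   depth = 1100 + cumsum(stats::rnorm(n, 0, 0.3)))
  ph <- rep("at_depth", n)
  th <- 0.83
  tr2 <- tr
  tr2$x <- cos(th) * tr$x - sin(th) * tr$y + 5000
  tr2$y <- sin(th) * tr$x + cos(th) * tr$y - 2000
  expect_equal(swim_speeds(tr2, ph)$at_depth_mps,
               swim_speeds(tr, ph)$at_depth_mps, tolerance = 1e-9)
})

test_that("track_metrics summarizes a simulated dive sensibly", {
  b <- flat_bathy()
  tr <- simulate_dive(dive_config(duration_s = 2400), b, seed = 5)
  m <- track_metrics(list(w1 = tr), b)
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$descent_angle_deg + 68.8), 3)
  expect_gt(m$median_altitude_m, 50)
  expect_lt(m$median_altitude_m, 200)
  expect_equal(m$at_depth_speed_mps, 1.25, tolerance = 0.05)
})
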