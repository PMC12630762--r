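# dive simulation, click emission, propagation/detection, click waveforms

test_that("noiseless dive descends at exactly the configured angle", {
  b <- flat_bathy()
  tr <- simulate_dive(dive_config(noiseless = TRUE), b, seed = 1)
  seg <- atan2(-diff(tr$depth), sqrt(diff(tr$x)^2 + diff(tr$y)^2)) * 180 / pi
  desc <- tr$phase[-1] == "descent" & tr$phase[-nrow(tr)] == "descent"
  expect_true(all(abs(seg[desc] + 68.8) < 1e-6))
})

test_that("at-depth samples stay inside the configured altitude band", {
  b <- flat_bathy(depth = 1300)
  tr <- simulate_dive(dive_config(altitude_band = c(50, 200)), b, seed = 3)
  ad <- tr$depth[tr$phase == "at_depth"]
  expect_true(all(ad >= 1100 - 1e-9 & ad <= 1250 + 1e-9))
})

test_that("dive simulation is deterministic per seed and validates its start", {
  b <- flat_bathy()
  t1 <- simulate_dive(dive_config(), b, seed = 42)
  t2 <- simulate_dive(dive_config(), b, seed = 42)
  expect_identical(t1, t2)
  t3 <- simulate_dive(dive_config(), b, seed = 43)
  expect_false(identical(t1, t3))
  expect_error(simulate_dive(dive_config(start_xy = c(99999, 0)), b, 1),
               "outside bathymetry")
})

test_that("echolocation flag is on exactly below the click start depth", {
  b <- flat_bathy()
  tr <- simulate_dive(dive_config(click_start_depth = 400), b, seed = 9)
  expect_identical(tr$echolocating, tr$depth >= 400)
})

test_that("click emission matches duration/ICI and follows the velocity axis", {
  # synthetic trajectory: eastbound at 2 m/s, echolocating for 600 s
  tr <- data.frame(whale_id = "w", time = 0:600, x = 2 * (0:600), y = 0,
                   depth = 1000, echolocating = TRUE, phase = "at_depth")
  cl <- emit_clicks(tr, inter_click_interval = 0.4, seed = 1)
  expect_lte(abs(nrow(cl) - 1500), 1)
  expect_true(all(diff(cl$emit_time) > 0))
  expect_equal(cl$ax, rep(1, nrow(cl)), tolerance = 1e-12)
  expect_equal(cl$ay, rep(0, nrow(cl)), tolerance = 1e-12)
  expect_true(all(cl$source_level >= 221 & cl$source_level <= 223))
  expect_true(all(cl$directivity_index >= 23 & cl$directivity_index <= 25))
})

test_that("a silent trajectory yields an empty click table, not an error", {
  tr <- data.frame(whale_id = "w", time = 0:100, x = 0, y = 0, depth = 100,
                   echolocating = FALSE, phase = "descent")
  cl <- emit_clicks(tr, 0.4, seed = 1)
  expect_equal(nrow(cl), 0L)
})

test_that("received level follows SL - TL - off-axis loss with the 112 dB threshold inclusive", {
  env <- make_environment(absorption_coeff = 0.01)
  arr <- list(tetrahedral_array(c(0, 0, -1000), array_id = "A"))
  # on-axis click at r = 1000 m: TL = 20 log10(1000) + 0.01*1000 = 70 dB
  click <- data.frame(whale_id = "w", emit_time = 0, x = 1000, y = 0,
                      depth = 1000, ax = -1, ay = 0, az = 0,
                      source_level = 222, directivity_index = 24)
  det <- propagate_and_detect(click, arr, env, tl_spherical(0.01),
                              tdoa_jitter_sd = 0)
  expect_equal(nrow(det), 1L)
  expect_equal(det$received_level, 152, tolerance = 1e-9)
  expect_equal(det$off_axis_deg, 0, tolerance = 1e-9)
  expect_equal(det$arrival_time, 1000 / 1500, tolerance = 1e-12)

  # exact threshold: RL = 112.0 detected, fractionally below is not
  env0 <- make_environment(absorption_coeff = 0)
  r_at <- 10^((222 - 112) / 20)              # SL - 20 log10(r) = 112
  for (cse in list(c(r_at, 1L), c(r_at * 10^(0.01 / 20), 0L))) {
    click$x <- cse[1]
    d <- propagate_and_detect(click, arr, env0, tl_spherical(0),
                              tdoa_jitter_sd = 0, beam = "omni")
    expect_equal(nrow(d), cse[2])
  }
})

test_that("zero range is an error and every click is kept when the threshold is -Inf", {
  env <- make_environment()
  arr <- array_pair()
  b <- flat_bathy()
  tr <- simulate_dive(dive_config(duration_s = 900), b, seed = 2)
  cl <- emit_clicks(tr, 1, seed = 2)
  det <- propagate_and_detect(cl, arr, env, threshold_db = -Inf,
                              tdoa_jitter_sd = 0)
  expect_equal(nrow(det), 2L * nrow(cl))       # conservation on both arrays
  bad <- cl[1, ]; bad$x <- arr[[1]]$origin[1]; bad$y <- arr[[1]]$origin[2]
  bad$depth <- -arr[[1]]$origin[3]
  expect_error(propagate_and_detect(bad, arr, env), "zero range")
})

test_that("an on-axis detected click stays detected at any smaller range", {
  env <- make_environment()
  arr <- list(tetrahedral_array(c(0, 0, -1000), array_id = "A"))
  ranges <- seq(3000, 100, by = -100)
  det <- sapply(ranges, function(r) {
    click <- data.frame(whale_id = "w", emit_time = 0, x = r, y = 0,
                        depth = 1000, ax = -1, ay = 0, az = 0,
                        source_level = 221, directivity_index = 24)
    nrow(propagate_and_detect(click, arr, env, tdoa_jitter_sd = 0))
  })
  expect_true(all(diff(det) >= 0))             # once detected, always closer
})

test_that("true TDOAs close to machine precision before jitter", {
  env <- make_environment()
  arr <- array_pair()
  click <- data.frame(whale_id = "w", emit_time = 0, x = 300, y = 700,
                      depth = 1150, ax = 0, ay = -1, az = 0,
                      source_level = 223, directivity_index = 23)
  det <- propagate_and_detect(click, arr, env, threshold_db = -Inf,
                              tdoa_jitter_sd = 0)
  expect_lt(max(abs(det$tdoa_12 + det$tdoa_23 - det$tdoa_13)), 1e-12)
  expect_lt(max(abs(det$tdoa_13 + det$tdoa_34 - det$tdoa_14)), 1e-12)
})

test_that("synthesized clicks place energy in band and support TDOA recovery", {
  env <- make_environment()
  det <- list(received_level = 130, tdoa_12 = 7e-5, tdoa_13 = 0, tdoa_14 = 0)
  w <- synthesize_click_waveform(det, env, 256)
  expect_equal(dim(w), c(256L, 4L))
  # tau_12 = 7 samples: channel 1 arrives 7 samples after channel 2
  m <- measure_tdoa(w, env$sample_rate, highpass_cutoff = 0)
  expect_equal(m$tdoas[1], 7e-5, tolerance = 1e-7)
  # >= 90% of spectral energy within 20-60 kHz (two-sided spectrum)
  s <- w[, 1]
  S <- Mod(stats::fft(s))^2
  fr <- (seq_along(s) - 1) / length(s) * env$sample_rate
  inband <- (fr >= 20e3 & fr <= 60e3) |
    (fr >= env$sample_rate - 60e3 & fr <= env$sample_rate - 20e3)
  expect_gt(sum(S[inband]) / sum(S), 0.9)
  expect_error(synthesize_click_waveform(det, env, 8), "shorter than")
})

test_that("transmission-loss tables interpolate in range and depth", {
  f <- withr::local_tempfile(fileext = ".csv")
  g <- expand.grid(range_m = c(100, 1000, 2000), source_depth_m = c(500, 1500))
  g$tl_db <- 20 * log10(g$range_m) + 0.001 * g$source_depth_m
  utils::write.csv(g, f, row.names = FALSE)
  tl <- tl_from_table(f)
  expect_equal(tl(1000, 500), 60.5, tolerance = 1e-9)
  expect_equal(tl(1500, 1000), mean(c(20 * log10(1000), 20 * log10(2000))) + 1,
               tolerance = 1e-9)
  # 1D table
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(range_m = c(1, 10, 100),
                              tl_db = c(0, 20, 40)), f2, row.names = FALSE)
  tl2 <- tl_from_table(f2)
  expect_equal(tl2(55), 30, tolerance = 1e-9)
})
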