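# group size, pairs/lane distance, closest-approach lag, subgrouping,
# track density

test_that("group size merges cross-array identities", {
  p <- data.frame(train_a = "w2", train_b = "w2b")
  expect_equal(group_size(c("w1", "w2"), c("w2b", "w3"), p), 3L)
  expect_equal(group_size("w1", character(0)), 1L)
  full <- data.frame(train_a = c("a", "b", "c"), train_b = c("a", "b", "c"))
  expect_equal(group_size(c("a", "b", "c"), c("a", "b", "c"), full), 3L)
  bad <- data.frame(train_a = c("a", "a"), train_b = c("x", "y"))
  expect_error(group_size(c("a", "b"), c("x", "y"), bad), "paired more than once")
})

test_that("pairs distance: static whales 300 m apart give constant minute bins", {
  t <- seq(0, 600 - 1)
  a <- data.frame(time = t, x = 0, y = 0, depth = 1100)
  b <- data.frame(time = t, x = 300, y = 0, depth = 1100)
  pd <- pairs_distance(a, b)
  expect_equal(nrow(pd), 10L)
  expect_true(all(abs(pd$mean_distance_m - 300) < 1e-12))
  # disjoint time ranges -> empty series
  b2 <- b; b2$time <- b2$time + 10000
  expect_equal(nrow(pairs_distance(a, b2)), 0L)
})

test_that("pairs distance matches brute force on converging tracks", {
  ta <- seq(0, 300, by = 2)
  tb <- seq(0.5, 300, by = 2.5)
  a <- data.frame(time = ta, x = ta, y = 0, depth = 1100)
  b <- data.frame(time = tb, x = 500 - tb, y = 40, depth = 1100 + 0.1 * tb)
  pd <- pairs_distance(a, b)
  # brute force: nearest b sample within 5 s for every a sample
  d <- rep(NA_real_, length(ta))
  for (i in seq_along(ta)) {
    j <- which.min(abs(tb - ta[i]))
    if (abs(tb[j] - ta[i]) <= 5)
      d[i] <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                     (a$depth[i] - b$depth[j])^2)
  }
  bins <- floor(ta / 60) * 60
  ref <- tapply(d[!is.na(d)], bins[!is.na(d)], mean)
  expect_equal(pd$mean_distance_m, as.numeric(ref), tolerance = 1e-9)
  # symmetric under whale swap
  pd2 <- pairs_distance(b, a)
  expect_equal(stats::median(pd$mean_distance_m),
               stats::median(pd2$mean_distance_m), tolerance = 5)
})

test_that("lane distance: parallel straight tracks read their separation", {
  t <- 0:500
  a <- data.frame(time = t, x = t, y = 0, depth = 1100)
  b <- data.frame(time = t, x = t, y = 100, depth = 1100)
  ld <- lane_distance(a, b)
  # interior bins (away from the ends) are exactly 100 m
  interior <- ld$bin_start_m > 20 & ld$bin_start_m < 460
  expect_true(all(abs(ld$mean_distance_m[interior] - 100) < 1e-9))
  # identical tracks -> zero everywhere
  ld0 <- lane_distance(a, a)
  expect_true(all(ld0$mean_distance_m < 1e-9))
})

test_that("lane distance dips to zero at a perpendicular crossing", {
  t <- seq(-250, 250)
  a <- data.frame(time = t + 250, x = t, y = 0, depth = 1100)
  b <- data.frame(time = t + 250, x = 0, y = t, depth = 1100)
  ld <- lane_distance(a, b)
  k <- which.min(ld$mean_distance_m)
  expect_lt(ld$mean_distance_m[k], 6)
  expect_equal(ld$bin_start_m[k], 250, tolerance = 10)
  # distance grows with arc distance from the crossing
  expect_true(all(diff(ld$mean_distance_m[ld$bin_start_m >= 260]) > -1e-9))
  expect_true(all(diff(ld$mean_distance_m[ld$bin_start_m <= 240]) < 1e-9))
})

test_that("lane distance agrees with a brute-force nearest-point scan", {
  set.seed(31)
  n <- 60
  a <- data.frame(time = 1:n, x = cumsum(stats::runif(n, 0.5, 2)),
                  y = cumsum(stats::rnorm(n)), depth = 1100)
  b <- data.frame(time = 1:n, x = cumsum(stats::runif(n, 0.5, 2)),
                  y = 150 + cumsum(stats::rnorm(n)), depth = 1120)
  ld <- lane_distance(a, b)
  ra <- resample_arclength(a, 1)
  rb <- resample_arclength(b, 1)
  brute <- sapply(seq_len(nrow(ra)), function(i)
    min(sqrt((rb$x - ra$x[i])^2 + (rb$y - ra$y[i])^2 + (rb$z - ra$z[i])^2)))
  ref <- tapply(brute, floor(ra$s / 10) * 10, mean)
  expect_equal(ld$mean_distance_m, as.numeric(ref), tolerance = 1e-9)
})

test_that("closest approach lag finds the minimizing pair and its time offset", {
  # A ends at t = 100 near the origin; B passes the origin at t = 160
  a <- data.frame(time = 0:100, x = seq(-200, 0, length.out = 101), y = 0,
                  depth = 1100)
  b <- data.frame(time = 110:260, x = 0, y = seq(-500, 1000, length.out = 151),
                  depth = 1100)
  r <- closest_approach_lag(a, b)
  expect_equal(r$lag_s, 60, tolerance = 1)
  expect_lt(r$distance_m, 10)
  # simultaneous closest approach -> zero lag
  r0 <- closest_approach_lag(a, data.frame(time = 0:100, x = a$x, y = 50,
                                           depth = 1100))
  expect_equal(r0$lag_s, 0)
  expect_equal(r0$distance_m, 50, tolerance = 1e-9)
})

test_that("closest approach matches an exhaustive scan on random tracks", {
  set.seed(32)
  for (k in 1:10) {
    a <- data.frame(time = sort(stats::runif(40, 0, 500)),
                    x = stats::rnorm(40, 0, 200), y = stats::rnorm(40, 0, 200),
                    depth = stats::runif(40, 1000, 1200))
    b <- data.frame(time = sort(stats::runif(35, 0, 500)),
                    x = stats::rnorm(35, 0, 200), y = stats::rnorm(35, 0, 200),
                    depth = stats::runif(35, 1000, 1200))
    r <- closest_approach_lag(a, b)
    dmin <- Inf; besti <- bestj <- NA
    for (i in 1:40) for (j in 1:35) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$depth[i] - b$depth[j])^2)
      if (d < dmin) { dmin <- d; besti <- i; bestj <- j }
    }
    expect_equal(r$distance_m, dmin, tolerance = 1e-9)
    expect_equal(r$lag_s, abs(a$time[besti] - b$time[bestj]), tolerance = 1e-9)
  }
})

test_that("subgrouping follows the 1000 m cutoff and the overlap rule", {
  D <- matrix(c(0, 400, 1500,
                400, 0, 1500,
                1500, 1500, 0), 3, 3,
              dimnames = list(c("w1", "w2", "w3"), c("w1", "w2", "w3")))
  sg <- find_subgroups(distances = D)
  expect_equal(sg$n_subgroups, 2L)
  expect_equal(unname(sg$labels["w1"]), unname(sg$labels["w2"]))
  expect_false(sg$labels["w1"] == sg$labels["w3"])
  # two whales 500 m apart in overlapping space-time -> one subgroup
  t <- 0:900
  a <- data.frame(time = t, x = 0, y = 0, depth = 1100)
  b <- data.frame(time = t, x = 500, y = 0, depth = 1100)
  sg2 <- find_subgroups(list(w1 = a, w2 = b))
  expect_equal(sg2$n_subgroups, 1L)
  expect_equal(sg2$mean_size, 2)
  # no temporal overlap within 10 min forces separate subgroups even at 0 m
  b2 <- a; b2$time <- b2$time + 900 + 601
  sg3 <- find_subgroups(list(w1 = a, w2 = b2))
  expect_equal(sg3$n_subgroups, 2L)
  expect_true(is.infinite(sg3$distance["w1", "w2"]))
  # within 10 minutes of each other counts as overlap (rule boundary)
  b3 <- a; b3$time <- b3$time + 900 + 599
  sg4 <- find_subgroups(list(w1 = a, w2 = b3))
  expect_false(is.infinite(sg4$distance["w1", "w2"]))
  expect_equal(unname(sg4$distance["w1", "w2"]), 0)  # same spot, 599 s apart
})

test_that("subgroup partitions match a from-scratch single-linkage oracle", {
  set.seed(33)
  for (k in 1:50) {
    n <- sample(2:6, 1)
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, 0, 2500)
    if (k %% 3 == 0) {
      ut <- which(upper.tri(D))
      D[sample(ut, max(1, length(ut) %/% 4))] <- Inf  # overlap-rule splits
    }
    D <- D + t(D)
    dimnames(D) <- list(paste0("w", 1:n), paste0("w", 1:n))
    sg <- find_subgroups(distances = D, distance_cutoff = 1000)
    oracle <- single_linkage_oracle(D, 1000)
    expect_true(same_partition(unname(sg$labels), oracle))
    expect_equal(sum(table(sg$labels)), n)      # sizes sum to group size
  }
})

test_that("extreme cutoffs give one subgroup or all singletons", {
  set.seed(34)
  n <- 5
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(10, 1, 5000)
  D <- D + t(D)
  expect_equal(find_subgroups(distances = D, distance_cutoff = Inf)$n_subgroups,
               1L)
  expect_equal(find_subgroups(distances = D, distance_cutoff = 0)$n_subgroups,
               n)
})

test_that("track density counts distinct whales once per bin", {
  t <- 0:100
  a <- data.frame(time = t, x = 5 * t, y = 5, depth = 1100)  # 500 m east
  g1 <- track_density(list(w1 = a), bin_size = 10)
  expect_equal(sum(g1$counts > 0), 51L)          # 50 crossed bins + end bin
  expect_true(all(g1$counts %in% c(0L, 1L)))
  g2 <- track_density(list(w1 = a, w2 = a), bin_size = 10)
  expect_equal(max(g2$counts), 2L)
  expect_equal(g2$counts > 0, g1$counts > 0)
  # against brute-force membership of the densified points
  set.seed(35)
  b <- data.frame(time = 0:50, x = cumsum(stats::rnorm(51, 0, 8)),
                  y = cumsum(stats::rnorm(51, 0, 8)), depth = 1100)
  g3 <- track_density(list(w1 = b), bin_size = 10, densify = FALSE)
  xe <- g3$x_edges; ye <- g3$y_edges
  ref <- matrix(0L, length(xe) - 1, length(ye) - 1)
  for (i in seq_len(nrow(b))) {
    ix <- min(max(findInterval(b$x[i], xe, rightmost.closed = TRUE), 1),
              length(xe) - 1)
    iy <- min(max(findInterval(b$y[i], ye, rightmost.closed = TRUE), 1),
              length(ye) - 1)
    ref[ix, iy] <- 1L
  }
  expect_equal(g3$counts, ref)
  expect_equal(sum(track_density(list(), bin_size = 10)$counts), 0L)
})

test_that("time-lagged coordinated pairs have smaller lane than pairs distance", {
  # same path followed 120 s apart, 200 m lateral offset
  t <- 0:1200
  path_x <- 1.2 * t
  a <- data.frame(time = t, x = path_x, y = 0, depth = 1100)
  b <- data.frame(time = t, x = path_x - 1.2 * 120, y = 200, depth = 1100)
  pd <- pairs_distance(a, b)
  ld <- lane_distance(a, b)
  modal_pairs <- stats::median(pd$mean_distance_m)
  interior <- ld$bin_start_m > 150 & ld$bin_start_m < max(ld$bin_start_m) - 150
  modal_lane <- stats::median(ld$mean_distance_m[interior])
  expect_lt(modal_lane, modal_pairs)
  expect_equal(modal_lane, 200, tolerance = 1)
  expect_equal(modal_pairs, sqrt(200^2 + 144^2), tolerance = 1)
})
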