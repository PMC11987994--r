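mkTrack <- function(x, y = 0, z = 0, t = seq_along(x) - 1) {
  n <- length(x)
  FishTrack(data.frame(
    timestamp = parseFrameTimestamp("20250101_090000") + t,
    t_s = t, x_mm = x, y_mm = rep_len(y, n), z_mm = rep_len(z, n),
    x_delta_mm = 0, source = "fused", stringsAsFactors = FALSE))
}

test_that("step speeds follow the Euclidean displacement convention", {
  # stationary track: all zeros
  expect_equal(stepSpeeds(mkTrack(rep(5, 10)))$speed_mm_s, rep(0, 10))
  # 3-4-5 step: 5 mm/s
  tr <- FishTrack(data.frame(
    timestamp = parseFrameTimestamp("20250101_090000") + 0:1,
    t_s = 0:1, x_mm = c(0, 3), y_mm = c(0, 4), z_mm = 0,
    x_delta_mm = 0, source = "fused"))
  expect_equal(stepSpeeds(tr)$speed_mm_s, c(0, 5))
  # constant velocity: first is 0 by convention, rest are the speed
  cv <- stepSpeeds(mkTrack(seq(0, 90, by = 10)))
  expect_equal(cv$speed_mm_s, c(0, rep(10, 9)))
  # non-monotone time is an error
  bad <- trackData(mkTrack(1:3))
  bad$t_s <- c(0, 2, 1)
  expect_error(stepSpeeds(bad), "increasing")
})

test_that("total distance integrates speeds and is additive", {
  zero <- stepSpeeds(mkTrack(rep(1, 50)))
  expect_equal(totalDistance(zero), 0)
  # 36,000 samples at a constant 92.13 mm/s cover 3,316.68 m
  s <- data.frame(t_s = 0:35999, speed_mm_s = c(0, rep(92.13, 35999)))
  attr(s, "dt_s") <- 1
  expect_equal(totalDistance(s), 92.13 * 35999)
  expect_equal(totalDistance(s) / 1e3, 3316.7, tolerance = 1e-4)
  # concatenation additivity
  a <- mkTrack(c(0, 10, 30))
  b <- mkTrack(c(30, 35, 45), t = 2 + 0:2)
  ab <- mkTrack(c(0, 10, 30, 35, 45))
  expect_equal(totalDistance(stepSpeeds(ab)),
               totalDistance(stepSpeeds(a)) + totalDistance(stepSpeeds(b)))
})

test_that("windowing is non-overlapping with the trailing partial dropped", {
  mk <- function(n, val = 1) {
    s <- data.frame(t_s = 0:(n - 1), speed_mm_s = rep(val, n))
    attr(s, "dt_s") <- 1
    s
  }
  # a full 10-h, 1 Hz experiment reduces to exactly 3,600 windows
  expect_equal(nrow(windowMeans(mk(36000))), 3600)
  # 25 samples, window 10 -> 2 means, 5 dropped
  w <- windowMeans(mk(25))
  expect_equal(nrow(w), 2)
  # constant series: every mean is the constant
  expect_equal(windowMeans(mk(40, 7.5))$mean_speed_mm_s, rep(7.5, 4))
  # grand mean preserved when the length divides evenly
  set.seed(5)
  s <- data.frame(t_s = 0:199, speed_mm_s = runif(200, 0, 50))
  attr(s, "dt_s") <- 1
  expect_equal(mean(windowMeans(s)$mean_speed_mm_s),
               mean(s$speed_mm_s), tolerance = 1e-9)
  expect_error(windowMeans(mk(30), window_s = 3.5), "multiple")
})

test_that("occupancy grids conserve counts and localize mass", {
  corner <- mkTrack(rep(10, 25), y = 10, z = 10)
  g <- occupancy(corner, bins_per_axis = 5)
  expect_equal(sum(g$counts), 25)
  expect_equal(sum(g$counts > 0), 1)           # single corner bin
  expect_equal(g$counts[1, 1, 1], 25L)
  # full-track slice count equals the track length
  set.seed(9)
  geom <- TankGeometry()
  rnd <- mkTrack(runif(400, 0, geom@width_mm),
                 y = runif(400, 0, geom@water_mm),
                 z = runif(400, 0, geom@depth_mm))
  expect_equal(sum(occupancy(rnd, bins_per_axis = 4)$counts), 400)
  # slicing partitions the counts
  g1 <- occupancy(rnd, slice_hours = c(0, 400 / 2 / 3600), 4)
  g2 <- occupancy(rnd, slice_hours = c(400 / 2 / 3600, 1), 4)
  expect_equal(g1$n + g2$n, 400)
  # uniform occupancy: relative count spread shrinks with n
  set.seed(10)
  big <- mkTrack(runif(1e5, 0, geom@width_mm),
                 y = runif(1e5, 0, geom@water_mm),
                 z = runif(1e5, 0, geom@depth_mm))
  cnt <- occupancy(big, bins_per_axis = 4)$counts
  expect_lt(sd(cnt) / mean(cnt), 0.1)
})

test_that("occupancy long export mirrors the grid", {
  tr <- mkTrack(rep(10, 7), y = 10, z = 10)
  g <- occupancy(tr, bins_per_axis = 3)
  long <- occupancyToLong(g)
  expect_equal(nrow(long), 27)
  expect_equal(sum(long$count), 7)
})

test_that("dose suppression lowers simulated travel monotonically", {
  geom <- TankGeometry()
  base <- MotionConfig(duration_s = 300, mean_speed_mm_s = 18,
                       speed_sd = 3, seed = 31)
  dist <- vapply(c(0, 0.1, 0.45, 0.75), function(s) {
    simulateTrajectory(doseProfile(base, s, aggregation = s / 2, geom),
                       geom)$distance_mm
  }, numeric(1))
  expect_true(all(diff(dist) < 0))
})
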