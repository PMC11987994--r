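test_that("trajectories are reproducible and stay inside the tank", {
  geom <- TankGeometry()
  m <- MotionConfig(duration_s = 400, seed = 17)
  g1 <- simulateTrajectory(m, geom)
  g2 <- simulateTrajectory(m, geom)
  expect_identical(g1$positions, g2$positions)
  # bounds over many seeds
  for (seed in 1:25) {
    p <- simulateTrajectory(MotionConfig(duration_s = 2000, seed = seed,
                                         mean_speed_mm_s = 40,
                                         speed_sd = 20),
                            geom)$positions
    expect_true(all(p$x_mm >= 0 & p$x_mm <= geom@width_mm))
    expect_true(all(p$y_mm >= 0 & p$y_mm <= geom@water_mm))
    expect_true(all(p$z_mm >= 0 & p$z_mm <= geom@depth_mm))
  }
})

test_that("distance follows the speed program", {
  geom <- TankGeometry()
  # zero speed: stationary, zero distance
  g0 <- simulateTrajectory(MotionConfig(duration_s = 50,
                                        mean_speed_mm_s = 0, speed_sd = 0,
                                        seed = 1), geom)
  expect_equal(g0$distance_mm, 0)
  expect_equal(nrow(unique(g0$positions[, 2:4])), 1)
  # fixed 10 mm/s for 1,000 s with no wall encounters (vast arena):
  # distance within 1% of 10,000 mm by construction
  vast <- TankGeometry(1e6, 1e6, 1e6, 1e6)
  g1 <- simulateTrajectory(MotionConfig(duration_s = 1001,
                                        mean_speed_mm_s = 10, speed_sd = 0,
                                        turn_persistence = 0.99, seed = 2),
                           vast)
  expect_lt(abs(g1$distance_mm - 10000) / 10000, 0.01)
  # in the real tank, reflections can only shorten chords, never add
  g2 <- simulateTrajectory(MotionConfig(duration_s = 1001,
                                        mean_speed_mm_s = 10, speed_sd = 0,
                                        turn_persistence = 0.99, seed = 2),
                           geom)
  steps <- sqrt(rowSums(diff(as.matrix(g2$positions[, 2:4]))^2))
  expect_true(all(steps <= 10 + 1e-9))
})

test_that("dose profiles scale speed and shift the vertical preference", {
  base <- MotionConfig(mean_speed_mm_s = 100, bottom_bias = 0.2)
  expect_equal(doseProfile(base, 0)@mean_speed_mm_s, 100)
  expect_equal(doseProfile(base, 0)@bottom_bias, base@bottom_bias)
  expect_equal(doseProfile(base, 0.5)@mean_speed_mm_s, 50)
  expect_equal(doseProfile(base, 1)@mean_speed_mm_s, 0)
  d <- doseProfile(base, 0.5, aggregation = 0.8)
  expect_lt(d@bottom_bias, base@bottom_bias)   # pushed toward the surface
  expect_equal(d@home_strength, 0.8)
  expect_true(all(is.finite(d@home_mm)))
  # aggregated fish ends up nearer the surface on average
  geom <- TankGeometry()
  yfree <- mean(simulateTrajectory(
    MotionConfig(duration_s = 600, seed = 3), geom)$positions$y_mm)
  yagg <- mean(simulateTrajectory(
    doseProfile(MotionConfig(duration_s = 600, seed = 3), 0,
                aggregation = 0.9, geom), geom)$positions$y_mm)
  expect_gt(yagg, yfree)
})

test_that("rendering places the fish where the calibration says", {
  geom <- TankGeometry()
  scene <- smallScene(geom)
  centre <- data.frame(t_s = 0:1,
                       x_mm = geom@width_mm / 2,
                       y_mm = geom@water_mm / 2,
                       z_mm = geom@depth_mm / 2)
  gt <- structure(list(positions = centre, distance_mm = 0,
                       config = MotionConfig(duration_s = 2), geom = geom),
                  class = "GroundTruth")
  r <- renderViews(gt, scene)
  for (vw in c("front", "top")) {
    cal <- slot(scene, paste0("cal_", vw))
    vmm <- if (vw == "front") geom@water_mm / 2 else geom@depth_mm / 2
    want <- mmToPx(cal, geom, geom@width_mm / 2, vmm)
    expect_equal(r$truth[1, paste0(vw, "_u_px")], want$u)
    # centre of mass of the drawn fish matches the target to half a pixel
    px <- framePixels(r[[vw]][[1]])
    fish <- which(px == scene@fish_intensity, arr.ind = TRUE)
    com_u <- mean(fish[, 2] - 0.5) - cal@roi[1]
    com_v <- mean(fish[, 1] - 0.5) - cal@roi[2]
    expect_lt(abs(com_u - want$u), 0.5)
    expect_lt(abs(com_v - want$v), 0.5)
  }
  # reference carries the artifact but no fish
  scene2 <- smallScene(geom, artifact_rect = c(10, 10, 30, 20),
                       artifact_intensity = 240)
  r2 <- renderViews(gt, scene2)
  ref <- framePixels(r2$reference_front)
  expect_true(any(ref == 240))
  expect_false(any(ref == scene2@fish_intensity))
  frame1 <- framePixels(r2$front[[1]])
  expect_true(any(frame1 == scene2@fish_intensity))
  # artifact identical in frame and reference
  expect_equal(frame1[11:20, 11:30], ref[11:20, 11:30])
})

test_that("pixel noise adds in quadrature between renders", {
  geom <- TankGeometry()
  scene <- smallScene(geom, noise_sd = 5)
  pos <- data.frame(t_s = 0, x_mm = 270, y_mm = 100, z_mm = 185)
  gt <- structure(list(positions = pos, distance_mm = 0,
                       config = MotionConfig(duration_s = 1), geom = geom),
                  class = "GroundTruth")
  set.seed(1)
  a <- framePixels(renderViews(gt, scene)$front[[1]])
  b <- framePixels(renderViews(gt, scene)$front[[1]])
  expect_equal(sd(a - b), sqrt(2) * 5, tolerance = 0.05)
})

test_that("disk rendering writes streamable timestamped frames", {
  td <- withr::local_tempdir()
  geom <- TankGeometry()
  mc <- MotionConfig(duration_s = 5, seed = 6)
  gt <- simulateTrajectory(mc, geom)
  res <- renderViews(gt, smallScene(geom), out_dir = td)
  expect_length(list.files(res$front_dir, pattern = "^2025.*png$"), 5)
  expect_true(file.exists(res$reference_top))
  expect_true(file.exists(res$gt_csv))
  gtcsv <- read.csv(res$gt_csv)
  expect_equal(nrow(gtcsv), 5)
  # written frames read back to the rendered intensities
  px <- readImagePixels(list.files(res$front_dir, pattern = "^2025",
                                   full.names = TRUE)[1])
  expect_equal(dim(px), c(180, 320))
  expect_true(any(abs(px - 40) < 1))           # fish intensity survives I/O
})
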