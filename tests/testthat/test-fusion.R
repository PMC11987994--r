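mkDet <- function(stamps, u, v, status = "detected", view = "front") {
  data.frame(timestamp = stamps, view = view, u_px = u, v_px = v,
             area_px = 100, angle_deg = 0, status = status,
             stringsAsFactors = FALSE)
}

t0 <- parseFrameTimestamp("20250101_090000")

test_that("timestamp matching joins the views and reports gaps", {
  s <- t0 + 0:9
  m <- matchByTimestamp(mkDet(s, 1:10, 1:10),
                        mkDet(s, 1:10, 1:10, view = "top"))
  expect_equal(nrow(m$pairs), 10)
  expect_length(m$unmatched_front, 0)
  # front missing one second: N-1 pairs plus one reported gap
  m2 <- matchByTimestamp(mkDet(s[-4], 1:9, 1:9),
                         mkDet(s, 1:10, 1:10, view = "top"))
  expect_equal(nrow(m2$pairs), 9)
  expect_equal(m2$unmatched_top, s[4])
  # duplicate timestamps are a hard error naming the offender
  dup <- mkDet(s[c(1, 1, 2)], 1:3, 1:3)
  expect_error(matchByTimestamp(dup, mkDet(s, 1:10, 1:10, view = "top")),
               "duplicate.*20250101_090000")
})

test_that("fusion averages X, takes Y from front and Z from top", {
  geom <- TankGeometry()
  calF <- ViewCalibration("front", c(0, 0, 540, 200), 1, 1, v_flip = TRUE)
  calT <- ViewCalibration("top", c(0, 0, 540, 370), 1, 1, v_flip = FALSE)
  pair <- data.frame(timestamp = t0, u_front = 270, v_front = 50,
                     status_front = "detected", u_top = 270, v_top = 100,
                     status_top = "detected", stringsAsFactors = FALSE)
  p <- fusePair(pair, calF, calT, geom)
  expect_equal(p$x_mm, 270)
  expect_equal(p$x_delta_mm, 0)
  expect_equal(p$y_mm, 150)     # v_flip: 200 - 50
  expect_equal(p$z_mm, 100)
  expect_equal(p$source, "fused")
  # disagreeing X: mean and absolute difference
  pair2 <- pair
  pair2$u_front <- 260; pair2$u_top <- 280
  p2 <- fusePair(pair2, calF, calT, geom)
  expect_equal(p2$x_mm, 270)
  expect_equal(p2$x_delta_mm, 20)
  # one view missing: carry the previous coordinates forward
  pair3 <- pair
  pair3$status_top <- "missing"
  p3 <- fusePair(pair3, calF, calT, geom, previous = p2)
  expect_equal(p3$source, "carried")
  expect_equal(p3$x_mm, p2$x_mm)
  expect_equal(p3$y_mm, p2$y_mm)
  # missing with no previous point: dropped
  expect_null(fusePair(pair3, calF, calT, geom, previous = NULL))
  # large X disagreement is a warning, not a rejection
  pair4 <- pair
  pair4$u_front <- 200; pair4$u_top <- 300
  expect_warning(fusePair(pair4, calF, calT, geom), "disagreement")
})

test_that("fused 3D positions match the rendered ground truth", {
  run <- renderSmallRun(duration_s = 25, seed = 23, mean_speed = 18,
                        speed_sd = 3)
  det <- trackBothViews(run)
  m <- matchByTimestamp(det$front, det$top)
  tr <- trackData(fuseTracks(m, run$scene@cal_front, run$scene@cal_top,
                             run$geom))
  fused <- tr[tr$source == "fused", ]
  # align on capture timestamps: the first frame has no flow predecessor,
  # so the track starts one second into the ground truth
  gt_t <- as.numeric(difftime(fused$timestamp,
                              parseFrameTimestamp(run$scene@t0),
                              units = "secs"))
  truth <- run$gt$positions[match(gt_t, run$gt$positions$t_s), ]
  # px-equivalent tolerance: 3 px at the front-view scale
  tol <- 3 / run$scene@cal_front@px_per_mm_u
  expect_lt(mean(abs(fused$x_mm - truth$x_mm)), tol)
  expect_lt(mean(abs(fused$y_mm - truth$y_mm)), tol)
  expect_lt(mean(abs(fused$z_mm - truth$z_mm)), tol)
  # both views see the same true X: tiny logged discrepancy
  expect_lt(mean(fused$x_delta_mm), 2 / run$scene@cal_front@px_per_mm_u)
  # track invariants hold
  expect_true(all(diff(tr$t_s) > 0))
})

test_that("carried fraction mirrors the fraction of motionless frames", {
  # stop-and-go: hold still (sub-threshold motion) for a known span
  geom <- smallGeom()
  scene <- smallScene()
  n <- 40
  xs <- c(seq(100, 300, length.out = 15), rep(300, 10),
          seq(300, 420, length.out = 15))
  pos <- data.frame(t_s = 0:(n - 1), x_mm = xs, y_mm = 100, z_mm = 180)
  gt <- structure(list(positions = pos,
                       distance_mm = sum(abs(diff(xs))),
                       config = MotionConfig(duration_s = n), geom = geom),
                  class = "GroundTruth")
  r <- renderViews(gt, scene)
  detF <- trackFrames(r$front, r$reference_front, scene@cal_front)
  detT <- trackFrames(r$top, r$reference_top, scene@cal_top)
  m <- matchByTimestamp(detF, detT)
  tr <- trackData(fuseTracks(m, scene@cal_front, scene@cal_top, geom))
  carried <- mean(tr$source == "carried")
  expected <- mean(diff(xs) == 0)   # motionless transitions
  expect_lt(abs(carried - expected), 0.02 + 1 / n)
})
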