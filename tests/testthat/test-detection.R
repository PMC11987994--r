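test_that("reference subtraction isolates scene changes", {
  ref <- matrix(200, 40, 60)
  expect_equal(subtractReference(ref, ref), matrix(0, 40, 60))
  f <- ref
  f[10:14, 20:24] <- 150                       # 50-intensity square
  d <- subtractReference(f, ref)
  expect_equal(sort(unique(as.vector(d))), c(0, 50))
  expect_true(all(d[10:14, 20:24] == 50))
  expect_equal(sum(d > 0), 25)
  expect_error(subtractReference(matrix(0, 10, 10), matrix(0, 10, 11)),
               "dimensions")
  # colour frames are converted to luminance after differencing
  arr <- array(200, c(20, 20, 3))
  arr2 <- arr
  arr2[5, 5, ] <- 100
  d2 <- subtractReference(arr2, arr)
  expect_equal(d2[5, 5], 100)
  expect_true(is.matrix(d2))
})

test_that("dense flow recovers known translations and ignores lighting", {
  set.seed(7)
  bg <- matrix(0, 120, 160)
  tex <- matrix(runif(1600, 0, 255), 40, 40)
  a <- bg; a[41:80, 41:80] <- tex
  # no motion: flow is essentially zero
  f0 <- denseFlow(a, a)
  expect_lt(unname(quantile(flowMagnitude(f0), 0.99)), 0.1)
  # translation by (+5, 0): median flow inside the moved patch in [4, 6]
  b <- bg; b[41:80, 46:85] <- tex
  fl <- denseFlow(a, b)
  expect_gt(median(fl$du[41:80, 46:85]), 4)
  expect_lt(median(fl$du[41:80, 46:85]), 6)
  expect_lt(abs(median(fl$dv[41:80, 46:85])), 1)
  # a pure global illumination step produces almost no flow
  f2 <- denseFlow(a, a + 5)
  expect_lt(mean(flowMagnitude(f2)), 0.5)
  f3 <- denseFlow(a, a - 5)
  expect_lt(mean(flowMagnitude(f3)), 0.5)
  expect_error(denseFlow(a, matrix(0, 10, 10)), "dimensions")
})

test_that("motion mask thresholds the flow magnitude inclusively", {
  z <- list(du = matrix(0, 8, 8), dv = matrix(0, 8, 8))
  class(z) <- "FlowField"
  expect_equal(sum(motionMask(z, 1)), 0)
  one <- z; one$du[3, 3] <- 2                  # magnitude = 2 x thresh
  m <- motionMask(one, 1)
  expect_equal(sum(m), 1)
  expect_equal(m[3, 3], 1L)
  allat <- z; allat$dv[] <- 1.5                # everything exactly at thresh
  expect_equal(sum(motionMask(allat, 1.5)), 64)
  expect_error(motionMask(z, 0))
})

test_that("dilation grows masks as brute-force morphology predicts", {
  blank <- matrix(0L, 30, 30)
  expect_equal(sum(edgeAndDilate(matrix(0, 30, 30))), 0)
  # single pixel, 3x3 brush, 1 iteration -> 3x3 block
  one <- blank; one[15, 15] <- 1L
  d1 <- fishTrack3D:::dilateMask(one, 3, 1)
  expect_equal(sum(d1), 9)
  expect_true(all(d1[14:16, 14:16] == 1))
  # hollow square outline, 2 iterations: thickened, area grows, stays closed
  sq <- blank
  sq[6:25, 6] <- 1L; sq[6:25, 25] <- 1L; sq[6, 6:25] <- 1L
  sq[25, 6:25] <- 1L
  d2 <- fishTrack3D:::dilateMask(sq, 3, 2)
  expect_gt(sum(d2), sum(sq))
  expect_true(all(d2[sq == 1] == 1))           # dilation is extensive
  expect_error(edgeAndDilate(matrix(0, 5, 5), canny_lo = 10, canny_hi = 5),
               "lo < hi")
  expect_error(edgeAndDilate(matrix(0, 5, 5), kernel_px = 4), "odd")
})

test_that("blob measurement matches the worked rectangle example", {
  m <- matrix(0L, 40, 40)
  m[6:25, 6:15] <- 1L    # 10 px wide (u), 20 px tall (v), origin (5, 5)
  d <- extractBlob(m)
  expect_equal(d$status, "detected")
  expect_equal(unname(d$centroid), c(10, 15))
  expect_equal(d$area_px, 200)
  expect_equal(d$angle_deg, 90)                # long axis vertical
  expect_equal(d$n_px, 200)
  # empty mask is a missing value, not an error
  expect_equal(extractBlob(matrix(0L, 10, 10))$status, "missing")
  # sub-threshold component is ignored
  expect_equal(extractBlob(m, min_area_px = 300)$status, "missing")
})

test_that("largest component wins and ties break deterministically", {
  m <- matrix(0L, 60, 60)
  m[5:9, 5:14] <- 1L                            # area 50
  m[30:49, 30:54] <- 1L                         # area 500
  d <- extractBlob(m, min_area_px = 10)
  expect_equal(unname(d$centroid), c(41.5, 39))  # the 500-px component
  # equal-area components: uppermost-leftmost bounding box wins
  m2 <- matrix(0L, 40, 40)
  m2[4:8, 4:8] <- 1L
  m2[20:24, 20:24] <- 1L
  d2 <- extractBlob(m2, min_area_px = 5)
  expect_equal(unname(d2$centroid), c(5.5, 5.5))
  # 8-connectivity joins diagonally touching pixels
  m3 <- matrix(0L, 10, 10)
  m3[2, 2] <- 1L; m3[3, 3] <- 1L
  d3 <- extractBlob(m3, min_area_px = 2)
  expect_equal(d3$status, "detected")
  expect_equal(d3$n_px, 2)
})

test_that("hull, area and centroid agree with brute-force oracles", {
  set.seed(101)
  for (rep in 1:200) {
    m <- randomBlobMask(sample(24:64, 1), sample(24:64, 1))
    if (sum(m) < 5) next
    d <- extractBlob(m, min_area_px = 5)
    comp <- oracleLargestComponent(m, min_area = 5)
    if (is.null(comp)) {
      expect_equal(d$status, "missing")
      next
    }
    o <- oracleBlobMeasure(comp[, 2] - 1, comp[, 1] - 1)
    expect_equal(d$area_px, o$area, tolerance = 1e-10)
    expect_equal(unname(d$centroid), o$centroid, tolerance = 1e-10)
    expect_equal(d$n_px, nrow(comp))
  }
})

test_that("detection is translation-equivariant across the ROI", {
  geom <- smallGeom()
  scene <- smallScene()
  cal <- scene@cal_front
  draw <- function(u, v) {
    px <- matrix(scene@bg_intensity, scene@height_px, scene@width_px)
    fishTrack3D:::drawEllipse(px, cal@roi[1] + u, cal@roi[2] + v,
                              12, 5, 0.4, scene@fish_intensity)
  }
  ref <- matrix(scene@bg_intensity, scene@height_px, scene@width_px)
  base <- c(60, 40)
  prev <- draw(base[1], base[2])
  d0 <- processFrame(prev, draw(base[1] + 10, base[2]), ref, cal)
  expect_equal(d0$status, "detected")
  for (shift in list(c(40, 0), c(0, 30), c(90, 25))) {
    prevS <- draw(base[1] + shift[1], base[2] + shift[2])
    curS <- draw(base[1] + 10 + shift[1], base[2] + shift[2])
    dS <- processFrame(prevS, curS, ref, cal)
    expect_equal(dS$status, "detected")
    expect_lt(max(abs(dS$centroid - d0$centroid - shift)), 1)
  }
})

test_that("the frame pipeline is motion-gated", {
  geom <- smallGeom()
  scene <- smallScene()
  cal <- scene@cal_front
  ref <- matrix(scene@bg_intensity, scene@height_px, scene@width_px)
  px1 <- fishTrack3D:::drawEllipse(ref, 100, 60, 12, 5, 0, 40)
  px2 <- fishTrack3D:::drawEllipse(ref, 108, 60, 12, 5, 0, 40)
  # first frame of a sequence: no predecessor, no detection
  expect_equal(processFrame(NULL, px2, ref, cal)$status, "missing")
  # immobile fish: no motion energy, no detection
  expect_equal(processFrame(px1, px1, ref, cal)$status, "missing")
  # 8 px displacement: detected within 3 px of the rendered centre
  d <- processFrame(px1, px2, ref, cal)
  expect_equal(d$status, "detected")
  truth <- c(108 - cal@roi[1], 60 - cal@roi[2])
  expect_lt(sqrt(sum((d$centroid - truth)^2)), 3)
})

test_that("rendered sequences are recovered with high detection accuracy", {
  run <- renderSmallRun(duration_s = 25, seed = 19, mean_speed = 18,
                        speed_sd = 3)
  det <- trackBothViews(run)
  for (vw in c("front", "top")) {
    d <- det[[vw]]
    eligible <- d[-1, ]                        # first frame has no flow
    expect_gte(mean(eligible$status == "detected"), 0.95)
    tru <- run$render$truth[-1, paste0(vw, c("_u_px", "_v_px"))]
    ok <- eligible$status == "detected"
    err <- sqrt((eligible$u_px - tru[[1]])^2 +
                  (eligible$v_px - tru[[2]])^2)
    expect_lte(mean(err[ok]), 3)
  }
})

test_that("a static scene with an artifact never triggers detections", {
  geom <- smallGeom()
  scene <- smallScene(artifact_rect = c(40, 30, 60, 45),
                      artifact_intensity = 235)
  mc <- MotionConfig(duration_s = 20, mean_speed_mm_s = 0, speed_sd = 0,
                     seed = 2)
  gt <- simulateTrajectory(mc, geom)           # stationary fish
  r <- renderViews(gt, scene)
  det <- trackFrames(r$front, r$reference_front, scene@cal_front)
  expect_true(all(det$status == "missing"))
})
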