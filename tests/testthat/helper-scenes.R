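# Shared fixture builders: small rendered scenes keep the unit tests fast;
# sizes are scaled-down versions of the 640x360 validation scenes.

smallGeom <- function() TankGeometry()

smallScene <- function(geom = smallGeom(), w = 320, h = 180, ...) {
  SceneConfig(geom, width_px = w, height_px = h, ...)
}

# simulate + render in memory; returns everything needed to score tracking
renderSmallRun <- function(duration_s = 30, seed = 11, mean_speed = 15,
                           speed_sd = 4, geom = smallGeom(),
                           scene = smallScene(geom), ...) {
  mc <- MotionConfig(duration_s = duration_s, mean_speed_mm_s = mean_speed,
                     speed_sd = speed_sd, seed = seed, ...)
  gt <- simulateTrajectory(mc, geom)
  r <- renderViews(gt, scene)
  list(gt = gt, render = r, scene = scene, geom = geom)
}

trackBothViews <- function(run, params = DetectionParams()) {
  list(front = trackFrames(run$render$front, run$render$reference_front,
                           run$scene@cal_front, params),
       top = trackFrames(run$render$top, run$render$reference_top,
                         run$scene@cal_top, params))
}

# random blob mask: a few overlapping filled discs on a small grid
randomBlobMask <- function(H = 48, W = 48, ndiscs = 3) {
  m <- matrix(0L, H, W)
  for (k in seq_len(ndiscs)) {
    ci <- runif(1, 8, H - 8); cj <- runif(1, 8, W - 8)
    r <- runif(1, 2, 6)
    ii <- matrix(seq_len(H), H, W)
    jj <- matrix(seq_len(W), H, W, byrow = TRUE)
    m[(ii - ci)^2 + (jj - cj)^2 <= r^2] <- 1L
  }
  m
}

randomGroups <- function(k = NULL, nmax = 12) {
  if (is.null(k)) k <- sample(2:4, 1)
  out <- lapply(seq_len(k), function(i)
    round(runif(sample(3:nmax, 1), 0, 20) * 2) / 2)  # forces ties
  names(out) <- paste0("g", seq_len(k))
  out
}
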