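#' Simulate a bounded fish trajectory
#'
#' Correlated random walk in the tank volume: the horizontal heading takes
#' persistent wrapped-normal increments, the pitch is mean-reverting with a
#' vertical preference set by \code{bottom_bias}, the per-step speed is a
#' zero-truncated normal draw, an optional attractor pulls the fish toward
#' a fixed point (stress-induced confinement), and the walls reflect. The
#' walk is fully reproducible for a given seed.
#'
#' @param m a [MotionConfig].
#' @param geom a [TankGeometry].
#' @return A \code{GroundTruth} object: list with \code{positions}
#'   (data.frame \code{t_s, x_mm, y_mm, z_mm}), \code{distance_mm} (sum of
#'   step lengths), \code{config} and \code{geom}.
#' @examples
#' gt <- simulateTrajectory(MotionConfig(duration_s = 60, seed = 7),
#'                          TankGeometry())
#' gt$distance_mm
#' @export
simulateTrajectory <- function(m, geom = TankGeometry()) {
  stopifnot(is(m, "MotionConfig"), is(geom, "TankGeometry"))
  set.seed(m@seed)
  n <- round(m@duration_s / m@dt_s)
  stopifnot(n >= 1)
  lo <- rep(m@margin_mm, 3)
  hi <- c(geom@width_mm, geom@water_mm, geom@depth_mm) - m@margin_mm
  if (any(hi <= lo)) stop("margin_mm leaves no usable volume")
  hasHome <- m@home_strength > 0 && all(is.finite(m@home_mm)) &&
             length(m@home_mm) == 3

  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- lo + stats::runif(3) * (hi - lo)
  theta <- stats::runif(1, 0, 2 * pi)
  phi <- 0
  sig_theta <- (1 - m@turn_persistence) * pi
  phi0 <- -m@bottom_bias * (pi / 4)
  for (t in seq_len(n - 1)) {
    theta <- theta + stats::rnorm(1, 0, sig_theta)
    phi <- 0.75 * phi + 0.25 * phi0 + stats::rnorm(1, 0, 0.2)
    phi <- max(min(phi, pi / 3), -pi / 3)
    sp <- abs(stats::rnorm(1, m@mean_speed_mm_s, m@speed_sd))
    dir <- c(cos(phi) * cos(theta), sin(phi), cos(phi) * sin(theta))
    if (hasHome) {
      hv <- m@home_mm - pos[t, ]
      hd <- sqrt(sum(hv^2))
      if (hd > 1e-9) {
        dir <- (1 - m@home_strength) * dir + m@home_strength * hv / hd
        dl <- sqrt(sum(dir^2))
        if (dl > 1e-9) dir <- dir / dl
      }
    }
    p <- pos[t, ] + sp * m@dt_s * dir
    # fold back into the usable box (reflecting walls)
    for (a in 1:3) {
      while (p[a] < lo[a] || p[a] > hi[a]) {
        if (p[a] < lo[a]) p[a] <- 2 * lo[a] - p[a]
        if (p[a] > hi[a]) p[a] <- 2 * hi[a] - p[a]
      }
    }
    pos[t + 1, ] <- p
    # re-derive heading from the effective displacement after reflection
    d <- pos[t + 1, ] - pos[t, ]
    dl <- sqrt(sum(d^2))
    if (dl > 1e-9) {
      theta <- atan2(d[3], d[1])
      phi <- asin(max(min(d[2] / dl, 1), -1))
    }
  }
  steps <- if (n > 1) sqrt(rowSums(diff(pos)^2)) else numeric(0)
  structure(list(positions = data.frame(t_s = (seq_len(n) - 1) * m@dt_s,
                                        x_mm = pos[, 1], y_mm = pos[, 2],
                                        z_mm = pos[, 3]),
                 distance_mm = sum(steps), config = m, geom = geom),
            class = "GroundTruth")
}

# filled rotated ellipse at continuous source-pixel centre (cu, cv);
# pixel centres sit at (col - 0.5, row - 0.5)
drawEllipse <- function(px, cu, cv, a, b, angle, intensity) {
  H <- nrow(px); W <- ncol(px)
  r <- ceiling(max(a, b)) + 1
  rows <- max(1, floor(cv - r)):min(H, ceiling(cv + r + 1))
  cols <- max(1, floor(cu - r)):min(W, ceiling(cu + r + 1))
  if (length(rows) == 0 || length(cols) == 0) return(px)
  uc <- cols - 0.5 - cu
  vc <- rows - 0.5 - cv
  ct <- cos(angle); st <- sin(angle)
  U <- matrix(uc, length(rows), length(cols), byrow = TRUE)
  V <- matrix(vc, length(rows), length(cols))
  inside <- ((U * ct + V * st) / a)^2 + ((-U * st + V * ct) / b)^2 <= 1
  sub <- px[rows, cols, drop = FALSE]
  sub[inside] <- intensity
  px[rows, cols] <- sub
  px
}

drawArtifact <- function(px, scene) {
  r <- scene@artifact_rect
  if (length(r) != 4 || any(!is.finite(r))) return(px)
  rows <- (r[2] + 1):r[4]
  cols <- (r[1] + 1):r[3]
  px[rows, cols] <- scene@artifact_intensity
  px
}

renderOneView <- function(gt, scene, cal, t_index, headings_uv) {
  px <- matrix(scene@bg_intensity, scene@height_px, scene@width_px)
  px <- drawArtifact(px, scene)
  p <- gt$positions[t_index, ]
  vmm <- if (cal@view == "front") p$y_mm else p$z_mm
  rp <- mmToPx(cal, gt$geom, p$x_mm, vmm)
  cu <- cal@roi[1] + rp$u
  cv <- cal@roi[2] + rp$v
  ang <- atan2(headings_uv[t_index, 2], headings_uv[t_index, 1])
  px <- drawEllipse(px, cu, cv, scene@fish_axes_px[1],
                    scene@fish_axes_px[2], ang, scene@fish_intensity)
  if (scene@noise_sd > 0)
    px <- pmin(pmax(px + matrix(stats::rnorm(length(px), 0,
                                             scene@noise_sd),
                                nrow(px)), 0), 255)
  list(px = px, u = rp$u, v = rp$v)
}

# per-view projected heading (du, dv in image axes) for ellipse orientation
viewHeadings <- function(gt, cal) {
  p <- gt$positions
  dx <- c(diff(p$x_mm), 0)
  dvm <- if (cal@view == "front") c(diff(p$y_mm), 0) else c(diff(p$z_mm), 0)
  n <- nrow(p)
  if (n > 1) { dx[n] <- dx[n - 1]; dvm[n] <- dvm[n - 1] }
  dv <- if (cal@v_flip) -dvm else dvm
  cbind(du = ifelse(abs(dx) + abs(dv) < 1e-9, 1, dx), dv = dv)
}

#' Render a ground-truth trajectory as two-view frame sequences
#'
#' Draws the fish as a filled oriented ellipse at its projected position in
#' each view (front: X/Y, top: X/Z), on a uniform lighter background, with
#' an optional static artifact present in every frame and in the reference
#' (emulating a constant camera reflection) and optional Gaussian pixel
#' noise. With \code{out_dir} set, frames are written incrementally as
#' timestamp-named grayscale PNGs (\code{front/}, \code{top/}, each with a
#' \code{reference.png}) together with \code{ground_truth.csv}; otherwise
#' frames are returned in memory.
#'
#' @param gt a \code{GroundTruth} from [simulateTrajectory].
#' @param scene a [SceneConfig]; its calibrations must refer to the same
#'   tank geometry.
#' @param out_dir output directory, or \code{NULL} for in-memory frames.
#' @return With \code{out_dir}: list with \code{front_dir}, \code{top_dir},
#'   \code{reference_front}, \code{reference_top}, \code{gt_csv} and the
#'   augmented \code{truth} data.frame (per-frame true centroids in ROI px
#'   per view). In memory: list with \code{front}, \code{top} (lists of
#'   [Frame]), \code{reference_front}, \code{reference_top} and
#'   \code{truth}.
#' @export
renderViews <- function(gt, scene, out_dir = NULL) {
  stopifnot(inherits(gt, "GroundTruth"), is(scene, "SceneConfig"))
  n <- nrow(gt$positions)
  stamps <- parseFrameTimestamp(scene@t0) + gt$positions$t_s
  hv <- list(front = viewHeadings(gt, scene@cal_front),
             top = viewHeadings(gt, scene@cal_top))
  cals <- list(front = scene@cal_front, top = scene@cal_top)
  refPx <- lapply(cals, function(cal)
    drawArtifact(matrix(scene@bg_intensity, scene@height_px,
                        scene@width_px), scene))
  truth <- cbind(gt$positions,
                 front_u_px = NA_real_, front_v_px = NA_real_,
                 top_u_px = NA_real_, top_v_px = NA_real_)
  toDisk <- !is.null(out_dir)
  if (toDisk) {
    dirs <- file.path(out_dir, c("front", "top"))
    for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
    writeImagePixels(refPx$front, file.path(dirs[1], "reference.png"))
    writeImagePixels(refPx$top, file.path(dirs[2], "reference.png"))
  } else {
    frames <- list(front = vector("list", n), top = vector("list", n))
  }
  for (t in seq_len(n)) {
    for (vw in c("front", "top")) {
      r <- renderOneView(gt, scene, cals[[vw]], t, hv[[vw]])
      truth[t, paste0(vw, "_u_px")] <- r$u
      truth[t, paste0(vw, "_v_px")] <- r$v
      if (toDisk) {
        writeImagePixels(r$px, file.path(
          out_dir, vw, paste0(formatFrameTimestamp(stamps[t]), ".png")))
      } else {
        frames[[vw]][[t]] <- Frame(r$px, stamps[t], vw)
      }
    }
  }
  if (toDisk) {
    gt_csv <- file.path(out_dir, "ground_truth.csv")
    writeCsv(truth, gt_csv)
    list(front_dir = file.path(out_dir, "front"),
         top_dir = file.path(out_dir, "top"),
         reference_front = file.path(out_dir, "front", "reference.png"),
         reference_top = file.path(out_dir, "top", "reference.png"),
         gt_csv = gt_csv, truth = truth)
  } else {
    list(front = frames$front, top = frames$top,
         reference_front = Frame(refPx$front, stamps[1], "front"),
         reference_top = Frame(refPx$top, stamps[1], "top"),
         truth = truth)
  }
}

#' Ground-truth trajectory as a track object
#'
#' Wraps a simulated trajectory in the fused-track container so the
#' trajectory metrics (speeds, windows, distance, occupancy) can be
#' computed directly on ground truth, bypassing rendering and detection.
#'
#' @param gt a \code{GroundTruth} from [simulateTrajectory].
#' @param t0 timestamp of the first sample, \code{YYYYMMDD_HHMMSS}.
#' @return A [FishTrack] with \code{source = "fused"} throughout.
#' @export
groundTruthTrack <- function(gt, t0 = "20250101_090000") {
  stopifnot(inherits(gt, "GroundTruth"))
  p <- gt$positions
  FishTrack(data.frame(
    timestamp = parseFrameTimestamp(t0) + p$t_s,
    t_s = p$t_s, x_mm = p$x_mm, y_mm = p$y_mm, z_mm = p$z_mm,
    x_delta_mm = 0, source = "fused", stringsAsFactors = FALSE),
    gt$geom)
}

#' Derive a dose-affected motion configuration
#'
#' Maps an ammonia-analog dose effect onto the motion model: locomotor
#' suppression scales the mean speed by \code{1 - suppression}, and
#' aggregation shifts the vertical preference toward the water surface and
#' switches on an attractor near the surface in the upper-right region of
#' the tank (the late-exposure confinement pattern).
#'
#' @param base a [MotionConfig].
#' @param suppression numeric in [0, 1]: 0 leaves the config unchanged, 1
#'   stops the fish.
#' @param aggregation numeric in [0, 1]: strength of the surface
#'   confinement.
#' @param geom [TankGeometry] used to place the attractor.
#' @return A [MotionConfig].
#' @examples
#' doseProfile(MotionConfig(mean_speed_mm_s = 100), suppression = 0.5)
#' @export
doseProfile <- function(base, suppression, aggregation = 0,
                        geom = TankGeometry()) {
  stopifnot(is(base, "MotionConfig"),
            suppression >= 0, suppression <= 1,
            aggregation >= 0, aggregation <= 1)
  bias <- base@bottom_bias - aggregation * (1 + base@bottom_bias)
  home <- if (aggregation > 0)
    c(0.75 * geom@width_mm, 0.85 * geom@water_mm, 0.75 * geom@depth_mm)
  else base@home_mm
  MotionConfig(duration_s = base@duration_s, dt_s = base@dt_s,
               mean_speed_mm_s = base@mean_speed_mm_s * (1 - suppression),
               speed_sd = base@speed_sd,
               turn_persistence = base@turn_persistence,
               bottom_bias = max(bias, -1), margin_mm = base@margin_mm,
               home_mm = home,
               home_strength = max(base@home_strength, aggregation),
               seed = base@seed)
}
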