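#' Tank geometry
#'
#' Physical extents of the rectangular glass tank. The tank frame is
#' right-handed with the origin at the front-left-bottom corner: X along the
#' long side (width), Y up from the tank bottom, Z along the short side
#' (depth). The fish can use the water column only, so the usable Y extent is
#' \code{water_mm}, not the wall height.
#'
#' @slot width_mm numeric, X extent of the tank (mm).
#' @slot depth_mm numeric, Z extent (mm).
#' @slot height_mm numeric, wall height (mm).
#' @slot water_mm numeric, water column height, the usable Y extent (mm).
#' @export
setClass("TankGeometry",
  representation(width_mm = "numeric", depth_mm = "numeric",
                 height_mm = "numeric", water_mm = "numeric"),
  validity = function(object) {
    v <- c(object@width_mm, object@depth_mm, object@height_mm,
           object@water_mm)
    if (length(v) != 4 || any(!is.finite(v)) || any(v <= 0))
      return("all extents must be single strictly positive numbers")
    if (object@water_mm > object@height_mm)
      return("water_mm must not exceed height_mm")
    TRUE
  })

#' @param width_mm,depth_mm,height_mm,water_mm tank extents in mm. Defaults
#'   are a 54 x 37 x 40 cm tank filled to 20 cm.
#' @return A \code{TankGeometry} object.
#' @examples
#' TankGeometry()
#' @rdname TankGeometry-class
#' @export
TankGeometry <- function(width_mm = 540, depth_mm = 370, height_mm = 400,
                         water_mm = 200) {
  new("TankGeometry", width_mm = width_mm, depth_mm = depth_mm,
      height_mm = height_mm, water_mm = water_mm)
}

setMethod("show", "TankGeometry", function(object) {
  cat(sprintf(
    "TankGeometry: %.0f x %.0f x %.0f mm (W x D x H), water %.0f mm\n",
    object@width_mm, object@depth_mm, object@height_mm, object@water_mm))
})

#' Per-view pixel/millimetre calibration
#'
#' Maps between image pixels and tank millimetres for one camera view.
#' The region of interest (\code{roi}) is the crop rectangle in source-pixel
#' coordinates, 0-based and half-open \code{[u0, u1) x [v0, v1)}. Pixel
#' coordinates handled by the mapping functions are relative to the ROI's
#' top-left corner. Scales are per-axis linear (no lens or refraction model).
#'
#' @slot view character, \code{"front"} (image axes map to tank X, Y) or
#'   \code{"top"} (X, Z).
#' @slot roi integer(4), crop rectangle \code{c(u0, v0, u1, v1)}.
#' @slot px_per_mm_u,px_per_mm_v numeric, pixels per millimetre along the
#'   horizontal and vertical image axes.
#' @slot v_flip logical; if \code{TRUE} the image v axis (downward) maps to
#'   decreasing tank Y, so \code{v = 0} is the water surface.
#' @export
setClass("ViewCalibration",
  representation(view = "character", roi = "numeric",
                 px_per_mm_u = "numeric", px_per_mm_v = "numeric",
                 v_flip = "logical"),
  validity = function(object) {
    if (!object@view %in% c("front", "top"))
      return("view must be 'front' or 'top'")
    r <- object@roi
    if (length(r) != 4 || any(!is.finite(r)) || any(r < 0))
      return("roi must be c(u0, v0, u1, v1), non-negative")
    if (r[3] <= r[1] || r[4] <= r[2])
      return("roi must be a non-empty half-open rectangle")
    if (object@px_per_mm_u <= 0 || object@px_per_mm_v <= 0)
      return("pixel scales must be strictly positive")
    TRUE
  })

#' @param view,roi,px_per_mm_u,px_per_mm_v,v_flip see slots.
#' @return A \code{ViewCalibration} object.
#' @rdname ViewCalibration-class
#' @export
ViewCalibration <- function(view, roi, px_per_mm_u, px_per_mm_v,
                            v_flip = identical(view, "front")) {
  new("ViewCalibration", view = view, roi = as.numeric(roi),
      px_per_mm_u = px_per_mm_u, px_per_mm_v = px_per_mm_v, v_flip = v_flip)
}

setMethod("show", "ViewCalibration", function(object) {
  cat(sprintf(
    "ViewCalibration (%s): ROI [%d,%d)x[%d,%d), %.3f/%.3f px per mm%s\n",
    object@view, object@roi[1], object@roi[3], object@roi[2], object@roi[4],
    object@px_per_mm_u, object@px_per_mm_v,
    if (object@v_flip) ", v flipped" else ""))
})

#' Detection pipeline parameters
#'
#' Tunable thresholds of the per-frame detection stage. Defaults are for
#' full-resolution (1920 x 1080) footage and transfer unchanged to the
#' reduced synthetic scenes used in the test-bench.
#'
#' @slot flow_mag_thresh numeric, minimum optical-flow magnitude (px/frame)
#'   for a pixel to count as moving.
#' @slot canny_lo,canny_hi numeric, Canny hysteresis thresholds on the Sobel
#'   gradient magnitude of the motion-gated difference image.
#' @slot canny_sigma numeric, Gaussian pre-smoothing for Canny (px).
#' @slot kernel_px integer, odd diameter of the disc dilation brush.
#' @slot dilate_iter integer, dilation iterations applied to the edge map.
#' @slot min_area_px numeric, minimum component area (px) to accept a blob.
#' @slot flow_levels,flow_iters integer, pyramid levels and per-level
#'   iterations of the dense flow estimator.
#' @slot flow_poly_sigma numeric and \code{flow_poly_radius},
#'   \code{flow_win_radius} integer: Gaussian applicability and aggregation
#'   window of the polynomial-expansion flow.
#' @export
setClass("DetectionParams",
  representation(flow_mag_thresh = "numeric", canny_lo = "numeric",
                 canny_hi = "numeric", canny_sigma = "numeric",
                 kernel_px = "numeric", dilate_iter = "numeric",
                 min_area_px = "numeric", flow_levels = "numeric",
                 flow_iters = "numeric", flow_poly_sigma = "numeric",
                 flow_poly_radius = "numeric", flow_win_radius = "numeric"),
  validity = function(object) {
    if (object@flow_mag_thresh <= 0) return("flow_mag_thresh must be > 0")
    if (!(object@canny_lo < object@canny_hi))
      return("canny thresholds must satisfy lo < hi")
    k <- object@kernel_px
    if (k < 3 || k %% 2 != 1) return("kernel_px must be odd and >= 3")
    if (object@dilate_iter < 0 || object@min_area_px < 0)
      return("dilate_iter and min_area_px must be non-negative")
    TRUE
  })

#' @param flow_mag_thresh,canny_lo,canny_hi,canny_sigma,kernel_px,dilate_iter,min_area_px,flow_levels,flow_iters,flow_poly_sigma,flow_poly_radius,flow_win_radius
#'   see slots.
#' @return A \code{DetectionParams} object.
#' @rdname DetectionParams-class
#' @export
DetectionParams <- function(flow_mag_thresh = 1.0, canny_lo = 50,
                            canny_hi = 150, canny_sigma = 1.0,
                            kernel_px = 3, dilate_iter = 2,
                            min_area_px = 50, flow_levels = 4,
                            flow_iters = 2, flow_poly_sigma = 1.5,
                            flow_poly_radius = 3, flow_win_radius = 6) {
  new("DetectionParams", flow_mag_thresh = flow_mag_thresh,
      canny_lo = canny_lo, canny_hi = canny_hi, canny_sigma = canny_sigma,
      kernel_px = kernel_px, dilate_iter = dilate_iter,
      min_area_px = min_area_px, flow_levels = flow_levels,
      flow_iters = flow_iters, flow_poly_sigma = flow_poly_sigma,
      flow_poly_radius = flow_poly_radius,
      flow_win_radius = flow_win_radius)
}

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf(paste0(
    "DetectionParams: flow >= %.2f px, Canny %g/%g, %dx%d disc x%d,",
    " min area %g px\n"),
    object@flow_mag_thresh, object@canny_lo, object@canny_hi,
    object@kernel_px, object@kernel_px, object@dilate_iter,
    object@min_area_px))
})

#' Motion model configuration for the trajectory simulator
#'
#' Parameters of the bounded correlated random walk that emulates a single
#' fish roaming the tank: persistent heading in the horizontal plane,
#' mean-reverting pitch with a vertical preference, reflecting walls, and an
#' optional attractor used to model stress-induced confinement near the
#' water surface.
#'
#' @slot duration_s numeric, trajectory length in seconds.
#' @slot dt_s numeric, time step (nominally 1 s, the capture rate).
#' @slot mean_speed_mm_s,speed_sd numeric, moments of the per-step speed
#'   draw (mm/s), truncated at zero.
#' @slot turn_persistence numeric in [0, 1): directional persistence of the
#'   horizontal heading; the per-step heading increment is wrapped-normal
#'   with sd \code{(1 - turn_persistence) * pi}.
#' @slot bottom_bias numeric in [-1, 1]: +1 pulls the pitch toward the tank
#'   bottom, -1 toward the water surface, 0 is neutral.
#' @slot margin_mm numeric, wall stand-off (mm) so the rendered body stays
#'   inside the view.
#' @slot home_mm numeric(3) or NA, optional attractor point (mm).
#' @slot home_strength numeric in [0, 1], pull toward the attractor.
#' @slot seed numeric, RNG seed; the trajectory is reproducible per seed.
#' @export
setClass("MotionConfig",
  representation(duration_s = "numeric", dt_s = "numeric",
                 mean_speed_mm_s = "numeric", speed_sd = "numeric",
                 turn_persistence = "numeric", bottom_bias = "numeric",
                 margin_mm = "numeric", home_mm = "numeric",
                 home_strength = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@duration_s <= 0 || object@dt_s <= 0)
      return("duration_s and dt_s must be positive")
    if (object@mean_speed_mm_s < 0 || object@speed_sd < 0)
      return("speeds must be non-negative")
    if (object@turn_persistence < 0 || object@turn_persistence >= 1)
      return("turn_persistence must lie in [0, 1)")
    if (abs(object@bottom_bias) > 1)
      return("bottom_bias must lie in [-1, 1]")
    if (object@home_strength < 0 || object@home_strength > 1)
      return("home_strength must lie in [0, 1]")
    TRUE
  })

#' @param duration_s,dt_s,mean_speed_mm_s,speed_sd,turn_persistence,bottom_bias,margin_mm,home_mm,home_strength,seed
#'   see slots.
#' @return A \code{MotionConfig} object.
#' @rdname MotionConfig-class
#' @export
MotionConfig <- function(duration_s = 600, dt_s = 1.0,
                         mean_speed_mm_s = 15, speed_sd = 4,
                         turn_persistence = 0.92, bottom_bias = 0,
                         margin_mm = 25, home_mm = NA_real_,
                         home_strength = 0, seed = 1) {
  new("MotionConfig", duration_s = duration_s, dt_s = dt_s,
      mean_speed_mm_s = mean_speed_mm_s, speed_sd = speed_sd,
      turn_persistence = turn_persistence, bottom_bias = bottom_bias,
      margin_mm = margin_mm, home_mm = home_mm,
      home_strength = home_strength, seed = seed)
}

setMethod("show", "MotionConfig", function(object) {
  cat(sprintf(paste0(
    "MotionConfig: %.0f s at %.1f Hz, speed %.1f +/- %.1f mm/s, ",
    "persistence %.2f, bottom bias %+.2f, seed %g\n"),
    object@duration_s, 1 / object@dt_s, object@mean_speed_mm_s,
    object@speed_sd, object@turn_persistence, object@bottom_bias,
    object@seed))
})

#' Scene configuration for the two-view renderer
#'
#' Describes how a ground-truth trajectory is turned into front- and
#' top-view image sequences: a dark elongated fish (filled oriented ellipse)
#' on a lighter background, an optional static artifact emulating the
#' constant camera reflection seen in real footage, and optional Gaussian
#' pixel noise.
#'
#' @slot width_px,height_px numeric, full image size per view.
#' @slot cal_front,cal_top \code{ViewCalibration} for the two views.
#' @slot fish_axes_px numeric(2), ellipse semi-axes (long, short) in px.
#' @slot fish_intensity,bg_intensity numeric in [0, 255]; they must differ
#'   by at least 20 so the fish is visible.
#' @slot noise_sd numeric, per-pixel Gaussian noise sd (intensity units).
#' @slot artifact_rect numeric(4) \code{c(u0, v0, u1, v1)} in source pixels
#'   or NA for none; drawn identically in every frame and the reference.
#' @slot artifact_intensity numeric in [0, 255].
#' @slot t0 character, timestamp of the first frame, \code{YYYYMMDD_HHMMSS}.
#' @export
setClass("SceneConfig",
  representation(width_px = "numeric", height_px = "numeric",
                 cal_front = "ViewCalibration", cal_top = "ViewCalibration",
                 fish_axes_px = "numeric", fish_intensity = "numeric",
                 bg_intensity = "numeric", noise_sd = "numeric",
                 artifact_rect = "numeric", artifact_intensity = "numeric",
                 t0 = "character"),
  validity = function(object) {
    if (object@width_px < 16 || object@height_px < 16)
      return("image size too small")
    if (length(object@fish_axes_px) != 2 || any(object@fish_axes_px <= 0))
      return("fish_axes_px must be two positive semi-axes")
    if (abs(object@fish_intensity - object@bg_intensity) < 20)
      return("fish and background intensity must differ by at least 20")
    if (object@noise_sd < 0) return("noise_sd must be non-negative")
    TRUE
  })

#' @param geom \code{TankGeometry} used to derive the per-view calibrations
#'   when none are supplied.
#' @param width_px,height_px,fish_axes_px,fish_intensity,bg_intensity,noise_sd,artifact_rect,artifact_intensity,t0,cal_front,cal_top
#'   see slots.
#' @return A \code{SceneConfig} object.
#' @rdname SceneConfig-class
#' @export
SceneConfig <- function(geom = TankGeometry(), width_px = 1920,
                        height_px = 1080,
                        cal_front = sceneCalibration(geom, width_px,
                                                     height_px, "front"),
                        cal_top = sceneCalibration(geom, width_px,
                                                   height_px, "top"),
                        fish_axes_px = c(18, 7), fish_intensity = 40,
                        bg_intensity = 200, noise_sd = 0,
                        artifact_rect = NA_real_, artifact_intensity = 230,
                        t0 = "20250101_090000") {
  new("SceneConfig", width_px = width_px, height_px = height_px,
      cal_front = cal_front, cal_top = cal_top,
      fish_axes_px = fish_axes_px, fish_intensity = fish_intensity,
      bg_intensity = bg_intensity, noise_sd = noise_sd,
      artifact_rect = as.numeric(artifact_rect),
      artifact_intensity = artifact_intensity, t0 = t0)
}

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf(paste0(
    "SceneConfig: %dx%d px, fish %gx%g px at %g on %g, noise sd %g%s\n"),
    object@width_px, object@height_px, object@fish_axes_px[1],
    object@fish_axes_px[2], object@fish_intensity, object@bg_intensity,
    object@noise_sd,
    if (all(is.finite(object@artifact_rect))) ", static artifact" else ""))
})

#' Fused 3D track
#'
#' Container for a per-second 3D trajectory in tank coordinates. The track
#' table has columns \code{timestamp} (POSIXct), \code{t_s} (seconds since
#' sequence start), \code{x_mm}, \code{y_mm}, \code{z_mm},
#' \code{x_delta_mm} (absolute front-vs-top X disagreement) and
#' \code{source} (\code{"fused"} or \code{"carried"}).
#'
#' @slot track data.frame as described above.
#' @slot geometry \code{TankGeometry} the coordinates refer to.
#' @export
setClass("FishTrack",
  representation(track = "data.frame", geometry = "TankGeometry"),
  validity = function(object) {
    need <- c("timestamp", "t_s", "x_mm", "y_mm", "z_mm", "x_delta_mm",
              "source")
    if (!all(need %in% names(object@track)))
      return(paste("track must have columns", paste(need, collapse = ", ")))
    tr <- object@track
    if (nrow(tr) > 0) {
      if (any(diff(tr$t_s) <= 0)) return("t_s must be strictly increasing")
      if (any(tr$t_s < 0)) return("t_s must be non-negative")
      if (any(tr$x_delta_mm < 0)) return("x_delta_mm must be >= 0")
    }
    TRUE
  })

#' @param track,geometry see slots.
#' @return A \code{FishTrack} object.
#' @rdname FishTrack-class
#' @export
FishTrack <- function(track, geometry = TankGeometry()) {
  new("FishTrack", track = track, geometry = geometry)
}

#' @rdname FishTrack-class
#' @param x,object a \code{FishTrack}.
#' @export
trackData <- function(x) {
  stopifnot(is(x, "FishTrack"))
  x@track
}

#' @rdname FishTrack-class
#' @export
trackGeometry <- function(x) {
  stopifnot(is(x, "FishTrack"))
  x@geometry
}

setMethod("length", "FishTrack", function(x) nrow(x@track))

setMethod("show", "FishTrack", function(object) {
  tr <- object@track
  cat(sprintf("FishTrack: %d points", nrow(tr)))
  if (nrow(tr) > 0) {
    cat(sprintf(", %.0f s span, %d carried (%.1f%%)",
                max(tr$t_s) - min(tr$t_s), sum(tr$source == "carried"),
                100 * mean(tr$source == "carried")))
  }
  cat("\n")
})
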