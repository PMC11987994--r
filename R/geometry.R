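#' @keywords internal
roiSize <- function(cal) {
  c(w = cal@roi[3] - cal@roi[1], h = cal@roi[4] - cal@roi[2])
}

# tank extents seen along the horizontal/vertical image axes of a view
viewExtents <- function(cal, geom) {
  if (cal@view == "front") c(u = geom@width_mm, v = geom@water_mm)
  else c(u = geom@width_mm, v = geom@depth_mm)
}

#' Map ROI pixel coordinates to tank millimetres
#'
#' Linear per-axis mapping from 0-based ROI pixel coordinates to tank
#' coordinates. The front view maps the horizontal image axis to tank X and
#' the vertical axis to tank Y (with \code{v_flip}, \code{v = 0} is the
#' water surface at \code{water_mm} and v increases downward); the top view
#' maps to X and Z. Mapped coordinates that overshoot the tank extents by a
#' small amount (edge detections can overshoot by a pixel) are clamped; the
#' returned object carries a \code{"clamped"} attribute marking affected
#' points.
#'
#' @param cal a [ViewCalibration].
#' @param geom a [TankGeometry].
#' @param u,v numeric vectors of pixel coordinates relative to the ROI's
#'   top-left corner; must lie within the (closed) ROI rectangle.
#' @return A data.frame with column \code{x_mm} plus \code{y_mm} (front) or
#'   \code{z_mm} (top); attribute \code{"clamped"} is a logical vector.
#' @examples
#' geom <- TankGeometry()
#' cal <- sceneCalibration(geom, 640, 360, "front")
#' pxToMm(cal, geom, u = 0, v = 0)   # left edge, water surface
#' @export
pxToMm <- function(cal, geom, u, v) {
  stopifnot(is(cal, "ViewCalibration"), is(geom, "TankGeometry"),
            length(u) == length(v))
  sz <- roiSize(cal)
  if (any(u < 0 | u > sz["w"] | v < 0 | v > sz["h"]))
    stop("pixel coordinates outside the calibration ROI")
  ext <- viewExtents(cal, geom)
  x <- u / cal@px_per_mm_u
  vv <- v / cal@px_per_mm_v
  if (cal@v_flip) vv <- ext["v"] - vv
  clamped <- x < 0 | x > ext["u"] | vv < 0 | vv > ext["v"]
  x <- pmin(pmax(x, 0), ext["u"])
  vv <- pmin(pmax(vv, 0), ext["v"])
  out <- if (cal@view == "front") {
    data.frame(x_mm = unname(x), y_mm = unname(vv))
  } else {
    data.frame(x_mm = unname(x), z_mm = unname(vv))
  }
  attr(out, "clamped") <- unname(clamped)
  out
}

#' Map tank millimetres to ROI pixel coordinates
#'
#' Exact inverse of [pxToMm] up to sub-pixel rounding; used by the synthetic
#' renderer to place the fish.
#'
#' @inheritParams pxToMm
#' @param x_mm numeric, tank X coordinates (mm).
#' @param vcoord_mm numeric, tank Y (front view) or Z (top view)
#'   coordinates (mm).
#' @return A data.frame with columns \code{u}, \code{v} (ROI pixels,
#'   sub-pixel).
#' @examples
#' geom <- TankGeometry()
#' cal <- sceneCalibration(geom, 640, 360, "top")
#' mmToPx(cal, geom, x_mm = 0, vcoord_mm = 0)  # tank corner
#' @export
mmToPx <- function(cal, geom, x_mm, vcoord_mm) {
  stopifnot(is(cal, "ViewCalibration"), is(geom, "TankGeometry"),
            length(x_mm) == length(vcoord_mm))
  ext <- viewExtents(cal, geom)
  if (any(x_mm < 0 | x_mm > ext["u"] | vcoord_mm < 0 |
          vcoord_mm > ext["v"]))
    stop("millimetre coordinates outside the tank extents")
  vv <- if (cal@v_flip) ext["v"] - vcoord_mm else vcoord_mm
  data.frame(u = unname(x_mm * cal@px_per_mm_u),
             v = unname(vv * cal@px_per_mm_v))
}

#' Derive a view calibration for a rendered scene
#'
#' Computes the largest centred ROI inside a \code{width_px x height_px}
#' image whose aspect ratio matches the tank extents visible in the given
#' view, with equal pixel scale on both axes. The front view shows tank
#' X (width) by Y (water height) and is v-flipped (image rows run from the
#' water surface down); the top view shows X by Z.
#'
#' @param geom a [TankGeometry].
#' @param width_px,height_px full image size.
#' @param view \code{"front"} or \code{"top"}.
#' @return A [ViewCalibration].
#' @examples
#' sceneCalibration(TankGeometry(), 640, 360, "front")
#' @export
sceneCalibration <- function(geom, width_px, height_px, view) {
  stopifnot(is(geom, "TankGeometry"), view %in% c("front", "top"))
  ext <- if (view == "front") c(geom@width_mm, geom@water_mm)
         else c(geom@width_mm, geom@depth_mm)
  s <- min(width_px / ext[1], height_px / ext[2])
  w <- floor(s * ext[1])
  h <- floor(s * ext[2])
  u0 <- floor((width_px - w) / 2)
  v0 <- floor((height_px - h) / 2)
  ViewCalibration(view = view, roi = c(u0, v0, u0 + w, v0 + h),
                  px_per_mm_u = w / ext[1], px_per_mm_v = h / ext[2],
                  v_flip = view == "front")
}
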