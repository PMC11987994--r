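#' A captured frame
#'
#' One still image from one view: a grayscale matrix or an H x W x 3 array
#' of intensities in [0, 255], tagged with its capture timestamp (parsed
#' from the \code{YYYYMMDD_HHMMSS} filename) and view.
#'
#' @slot pixels matrix (H x W) or array (H x W x 3), intensities in
#'   [0, 255].
#' @slot timestamp POSIXct, 1 s resolution.
#' @slot view character, \code{"front"} or \code{"top"}.
#' @export
setClass("Frame",
  representation(pixels = "ANY", timestamp = "POSIXct", view = "character"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (is.null(d) || length(d) < 2 || any(d[1:2] <= 0))
      return("pixels must be a non-empty matrix or H x W x 3 array")
    if (length(d) == 3 && d[3] != 3)
      return("colour frames must have 3 channels")
    if (!object@view %in% c("front", "top"))
      return("view must be 'front' or 'top'")
    TRUE
  })

#' @param pixels,timestamp,view see slots; \code{timestamp} may be a
#'   \code{YYYYMMDD_HHMMSS} string.
#' @return A \code{Frame}.
#' @rdname Frame-class
#' @export
Frame <- function(pixels, timestamp, view) {
  if (is.character(timestamp)) timestamp <- parseFrameTimestamp(timestamp)
  new("Frame", pixels = pixels, timestamp = timestamp, view = view)
}

setMethod("show", "Frame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Frame (%s) %dx%d%s @ %s\n", object@view, d[2], d[1],
              if (length(d) == 3) " rgb" else "",
              format(object@timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")))
})

#' @rdname Frame-class
#' @param x a \code{Frame}.
#' @export
framePixels <- function(x) {
  stopifnot(is(x, "Frame"))
  x@pixels
}

# luminance conversion for H x W x 3 arrays (ITU-R BT.601 weights)
toGray <- function(px) {
  if (length(dim(px)) == 3)
    0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  else px
}

#' Subtract the empty-tank reference image
#'
#' Per-pixel absolute difference between a frame and the reference image
#' taken while the tank was empty, converted to grayscale. Static scene
#' content (tank, lighting, constant reflections) cancels; the fish remains.
#'
#' @param frame,reference [Frame] objects of the same view and size, or raw
#'   pixel matrices/arrays.
#' @return A grayscale difference matrix in [0, 255].
#' @examples
#' f <- matrix(200, 32, 32); f[10:14, 10:14] <- 40
#' d <- subtractReference(f, matrix(200, 32, 32))
#' range(d)
#' @export
subtractReference <- function(frame, reference) {
  fp <- if (is(frame, "Frame")) frame@pixels else frame
  rp <- if (is(reference, "Frame")) reference@pixels else reference
  if (is(frame, "Frame") && is(reference, "Frame") &&
      frame@view != reference@view)
    stop("frame and reference views differ")
  if (!identical(dim(fp), dim(rp)))
    stop("frame and reference dimensions differ")
  toGray(abs(fp - rp))
}

#' Dense optical flow between consecutive grayscale frames
#'
#' Estimates per-pixel displacement mapping the earlier frame onto the
#' current one with a polynomial-expansion model (local quadratic fit under
#' a Gaussian applicability), refined coarse-to-fine over an image pyramid
#' so that displacements of tens of pixels -- typical at the 1 frame/s
#' capture rate -- are recovered.
#'
#' @param prev,cur grayscale matrices of identical size.
#' @param params a [DetectionParams] (flow settings are read from it).
#' @return An object of class \code{FlowField}: a list with H x W matrices
#'   \code{du} (horizontal) and \code{dv} (vertical), in px/frame.
#' @examples
#' a <- matrix(0, 48, 48); a[20:28, 10:18] <- 200
#' b <- matrix(0, 48, 48); b[20:28, 15:23] <- 200
#' fl <- denseFlow(a, b)
#' median(fl$du[20:28, 15:18])  # about +5
#' @export
denseFlow <- function(prev, cur, params = DetectionParams()) {
  if (!identical(dim(prev), dim(cur)))
    stop("frame dimensions differ")
  fl <- .denseFlowCpp(prev, cur,
                      levels = as.integer(params@flow_levels),
                      iters = as.integer(params@flow_iters),
                      poly_sigma = params@flow_poly_sigma,
                      poly_radius = as.integer(params@flow_poly_radius),
                      win_radius = as.integer(params@flow_win_radius))
  class(fl) <- "FlowField"
  fl
}

#' Flow magnitude image
#' @param flow a \code{FlowField} from [denseFlow].
#' @return Matrix of per-pixel flow magnitudes (px/frame).
#' @export
flowMagnitude <- function(flow) {
  sqrt(flow$du^2 + flow$dv^2)
}

#' Threshold a flow field into a motion mask
#'
#' @param flow a \code{FlowField}.
#' @param mag_thresh positive magnitude threshold (px/frame); pixels with
#'   magnitude \code{>= mag_thresh} (inclusive) are marked moving.
#' @return Binary matrix (0/1).
#' @export
motionMask <- function(flow, mag_thresh) {
  stopifnot(mag_thresh > 0)
  (flowMagnitude(flow) >= mag_thresh) * 1L
}

#' Canny edge detection
#'
#' Gaussian smoothing, 3 x 3 Sobel gradients, non-maximum suppression along
#' the quantized gradient direction, and hysteresis thresholding.
#'
#' @param img grayscale matrix.
#' @param lo,hi hysteresis thresholds on the gradient magnitude,
#'   \code{lo < hi}.
#' @param sigma Gaussian pre-smoothing sd (px).
#' @return Binary edge matrix.
#' @export
cannyEdges <- function(img, lo = 50, hi = 150, sigma = 1.0) {
  storage.mode(img) <- "double"
  m <- .cannyCpp(img, lo, hi, sigma)
  matrix(as.integer(m), nrow(img), ncol(img))
}

#' Edge detection plus morphological dilation
#'
#' Canny edges of the (typically motion-gated) grayscale image, dilated
#' with a disc brush so the fish outline closes into a solid region.
#'
#' @param img grayscale matrix (already motion-gated in the pipeline).
#' @param canny_lo,canny_hi hysteresis thresholds, \code{lo < hi}.
#' @param kernel_px odd brush diameter \code{>= 3}.
#' @param iterations dilation iterations.
#' @param sigma Canny pre-smoothing sd.
#' @return Binary matrix of the dilated edge region.
#' @export
edgeAndDilate <- function(img, canny_lo = 50, canny_hi = 150,
                          kernel_px = 3, iterations = 2, sigma = 1.0) {
  if (!(canny_lo < canny_hi)) stop("canny thresholds must satisfy lo < hi")
  if (kernel_px < 3 || kernel_px %% 2 != 1)
    stop("kernel_px must be odd and >= 3")
  edges <- cannyEdges(img, canny_lo, canny_hi, sigma)
  dilateMask(edges, kernel_px, iterations)
}

# binary dilation with a disc brush, repeated
dilateMask <- function(mask, kernel_px, iterations) {
  storage.mode(mask) <- "integer"
  if (iterations < 1 || sum(mask) == 0) return(mask)
  kern <- EBImage::makeBrush(kernel_px, shape = "disc")
  storage.mode(kern) <- "integer"
  .dilateCpp(mask, kern, as.integer(iterations))
}

# convex hull of the corner points of the listed pixels, in the continuous
# convention where pixel (u, v) spans [u, u+1) x [v, v+1). Returns the hull
# vertices counter-clockwise in (u, v).
pixelHull <- function(us, vs) {
  pts <- cbind(u = c(us, us + 1, us, us + 1),
               v = c(vs, vs, vs + 1, vs + 1))
  pts <- unique(pts)
  h <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise in (x, y)
  pts[rev(h), , drop = FALSE]
}

# shoelace signed area (positive for counter-clockwise vertex order)
polygonArea <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

polygonCentroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# minimum-area enclosing rectangle of a convex polygon (rotating calipers
# over edge directions); returns the long-side angle in [0, 180) degrees,
# measured from the +u axis (90 = vertical long axis).
minRectAngle <- function(poly) {
  n <- nrow(poly)
  best <- Inf; bestAngle <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    e <- poly[j, ] - poly[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    ct <- e[1] / len; st <- e[2] / len
    pu <- poly[, 1] * ct + poly[, 2] * st
    pv <- -poly[, 1] * st + poly[, 2] * ct
    du <- max(pu) - min(pu); dv <- max(pv) - min(pv)
    a <- du * dv
    if (a < best - 1e-12) {
      best <- a
      ang <- if (du >= dv) atan2(st, ct) else atan2(ct, -st)
      bestAngle <- (ang * 180 / pi) %% 180
    }
  }
  unname(bestAngle)
}

#' Measure the largest moving blob in a binary mask
#'
#' Selects the largest 8-connected foreground component with area at least
#' \code{min_area_px} (ties broken by the uppermost-leftmost bounding-box
#' origin), encloses it in the convex hull of its pixel squares (pixel
#' \code{(u, v)} spans \code{[u, u+1) x [v, v+1)}), and reports the hull's
#' area centroid, area, and the orientation of the long side of its
#' minimum-area enclosing rectangle.
#'
#' @param mask binary matrix (rows = v, columns = u).
#' @param min_area_px minimum component pixel count.
#' @param timestamp,view carried through to the result.
#' @return A list with \code{status} (\code{"detected"} or
#'   \code{"missing"}) and, when detected, \code{centroid} \code{c(u, v)}
#'   (sub-pixel, 0-based ROI coordinates), \code{area_px} (hull area),
#'   \code{angle_deg} in [0, 180), \code{polygon} (hull vertex matrix) and
#'   \code{n_px} (component pixel count).
#' @examples
#' m <- matrix(0L, 40, 40); m[6:25, 6:15] <- 1L   # 10 wide, 20 tall
#' d <- extractBlob(m)
#' d$centroid; d$area_px; d$angle_deg
#' @export
extractBlob <- function(mask, min_area_px = 50, timestamp = NA,
                        view = NA_character_) {
  missing <- list(status = "missing", timestamp = timestamp, view = view)
  storage.mode(mask) <- "integer"
  if (sum(mask) == 0) return(missing)
  lab <- .labelComponents8Cpp(mask)
  nlab <- max(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0) return(missing)
  big <- keep[sizes[keep] == max(sizes[keep])]
  if (length(big) > 1) {
    # tie-break: uppermost-leftmost bounding-box origin (v, then u)
    orig <- t(vapply(big, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      c(min(idx[, 1]), min(idx[, 2]))
    }, numeric(2)))
    big <- big[order(orig[, 1], orig[, 2])][1]
  }
  idx <- which(lab == big, arr.ind = TRUE)
  us <- idx[, 2] - 1  # 0-based u (column)
  vs <- idx[, 1] - 1  # 0-based v (row)
  hull <- pixelHull(us, vs)
  list(status = "detected", timestamp = timestamp, view = view,
       centroid = polygonCentroid(hull), area_px = abs(polygonArea(hull)),
       angle_deg = minRectAngle(hull), polygon = hull,
       n_px = length(us))
}

# crop a frame's pixels to a calibration ROI (0-based half-open rect)
cropToRoi <- function(px, cal) {
  r <- cal@roi
  d <- dim(px)
  if (r[3] > d[2] || r[4] > d[1])
    stop("calibration ROI exceeds the source image bounds")
  if (length(d) == 3) px[(r[2] + 1):r[4], (r[1] + 1):r[3], , drop = FALSE]
  else px[(r[2] + 1):r[4], (r[1] + 1):r[3], drop = FALSE]
}

#' Run the full detection pipeline on one frame
#'
#' Composition of the per-frame stages: crop to the calibrated ROI,
#' subtract the empty-tank reference, convert to grayscale, estimate dense
#' optical flow against the previous frame, threshold the flow into a
#' motion mask, gate the grayscale difference by the mask, extract Canny
#' edges, dilate them, and measure the largest blob. Detection is
#' motion-gated: the first frame of a sequence and frames without motion
#' energy yield \code{status = "missing"}.
#'
#' @param prev previous [Frame] (or pixel array) or \code{NULL} at the
#'   start of a sequence.
#' @param cur current [Frame] or pixel array.
#' @param reference empty-tank reference [Frame] or pixel array (full
#'   image, same size as the frames).
#' @param cal [ViewCalibration] whose ROI is applied to all three images.
#' @param params [DetectionParams].
#' @return As [extractBlob], with the frame's timestamp and view attached.
#' @export
processFrame <- function(prev, cur, reference, cal,
                         params = DetectionParams()) {
  ts <- if (is(cur, "Frame")) cur@timestamp else NA
  vw <- if (is(cur, "Frame")) cur@view else cal@view
  if (is(cur, "Frame") && cur@view != cal@view)
    stop("frame view does not match the calibration view")
  if (is.null(prev))
    return(list(status = "missing", timestamp = ts, view = vw))
  curPx <- cropToRoi(if (is(cur, "Frame")) cur@pixels else cur, cal)
  prevPx <- cropToRoi(if (is(prev, "Frame")) prev@pixels else prev, cal)
  refPx <- cropToRoi(if (is(reference, "Frame")) reference@pixels
                     else reference, cal)
  detectFromGrays(subtractReference(prevPx, refPx),
                  subtractReference(curPx, refPx), params, ts, vw)
}

# flow -> mask -> gated edges -> blob, on reference-subtracted grayscales
detectFromGrays <- function(prevGray, curGray, params, ts, vw) {
  fl <- denseFlow(prevGray, curGray, params)
  mm <- motionMask(fl, params@flow_mag_thresh)
  if (sum(mm) < params@min_area_px)
    return(list(status = "missing", timestamp = ts, view = vw))
  gated <- curGray * mm
  solid <- edgeAndDilate(gated, params@canny_lo, params@canny_hi,
                         params@kernel_px, params@dilate_iter,
                         params@canny_sigma)
  extractBlob(solid, params@min_area_px, ts, vw)
}

# one-row data.frame form of a detection (CSV currency)
detectionRow <- function(det) {
  if (det$status == "detected") {
    data.frame(timestamp = det$timestamp, view = det$view,
               u_px = det$centroid[1], v_px = det$centroid[2],
               area_px = det$area_px, angle_deg = det$angle_deg,
               status = "detected", stringsAsFactors = FALSE)
  } else {
    data.frame(timestamp = det$timestamp, view = det$view,
               u_px = NA_real_, v_px = NA_real_, area_px = NA_real_,
               angle_deg = NA_real_, status = "missing",
               stringsAsFactors = FALSE)
  }
}

#' Track a sequence of in-memory frames
#'
#' Applies [processFrame] along a time-ordered list of frames of one view.
#'
#' @param frames list of [Frame] objects (or pixel matrices), time-ordered.
#' @param reference empty-tank reference for the same view.
#' @param cal [ViewCalibration].
#' @param params [DetectionParams].
#' @return A detections data.frame with columns \code{timestamp},
#'   \code{view}, \code{u_px}, \code{v_px}, \code{area_px},
#'   \code{angle_deg}, \code{status}.
#' @export
trackFrames <- function(frames, reference, cal,
                        params = DetectionParams()) {
  refPx <- cropToRoi(if (is(reference, "Frame")) reference@pixels
                     else reference, cal)
  out <- vector("list", length(frames))
  prevGray <- NULL
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    ts <- if (is(f, "Frame")) f@timestamp else NA
    px <- cropToRoi(if (is(f, "Frame")) f@pixels else f, cal)
    curGray <- subtractReference(px, refPx)
    det <- if (is.null(prevGray)) {
      list(status = "missing", timestamp = ts, view = cal@view)
    } else {
      detectFromGrays(prevGray, curGray, params, ts, cal@view)
    }
    out[[i]] <- detectionRow(det)
    prevGray <- curGray
  }
  do.call(rbind, out)
}

#' Track a directory of timestamp-named frames
#'
#' Streams through \code{YYYYMMDD_HHMMSS.png} frames in time order, holding
#' only two frames in memory. Unreadable files are skipped with a warning
#' and counted in the result's \code{"n_skipped"} attribute.
#'
#' @param dir directory of PNG frames named by capture timestamp.
#' @param reference path to the empty-tank reference PNG (or a [Frame]).
#' @param cal [ViewCalibration].
#' @param params [DetectionParams].
#' @param name_format \code{\link{strptime}}-style timestamp pattern of the
#'   frame filenames (without extension).
#' @return Detections data.frame as in [trackFrames].
#' @export
trackDirectory <- function(dir, reference, cal,
                           params = DetectionParams(),
                           name_format = "%Y%m%d_%H%M%S") {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  files <- files[basename(files) != "reference.png"]
  if (length(files) == 0) stop("no frames found in ", dir)
  stamps <- parseFrameTimestamp(sub("\\.png$", "", basename(files)),
                                name_format)
  if (anyNA(stamps))
    stop("unparseable frame timestamps: ",
         paste(head(basename(files)[is.na(stamps)], 3), collapse = ", "))
  ord <- order(stamps)
  files <- files[ord]; stamps <- stamps[ord]
  refFull <- if (is(reference, "Frame")) reference@pixels
             else readImagePixels(reference)
  refPx <- cropToRoi(refFull, cal)
  out <- vector("list", length(files))
  prevGray <- NULL
  skipped <- 0L
  for (i in seq_along(files)) {
    px <- tryCatch(readImagePixels(files[i]), error = function(e) NULL)
    if (is.null(px)) {
      warning("skipping unreadable frame ", basename(files[i]))
      skipped <- skipped + 1L
      next
    }
    curGray <- subtractReference(cropToRoi(px, cal), refPx)
    det <- if (is.null(prevGray)) {
      list(status = "missing", timestamp = stamps[i], view = cal@view)
    } else {
      detectFromGrays(prevGray, curGray, params, stamps[i], cal@view)
    }
    out[[i]] <- detectionRow(det)
    prevGray <- curGray
  }
  res <- do.call(rbind, out)
  attr(res, "n_skipped") <- skipped
  res
}
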