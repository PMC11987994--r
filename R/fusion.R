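#' Match front- and top-view detections by timestamp
#'
#' Detections taken at the same second are combined into one record (inner
#' join on the exact timestamp); timestamps present in only one view are
#' reported, not silently dropped.
#'
#' @param front,top detections data.frames (as produced by [trackFrames] or
#'   [trackDirectory]), each sorted by timestamp.
#' @return A list with \code{pairs} (data.frame with \code{timestamp} and
#'   per-view columns suffixed \code{_front} / \code{_top}),
#'   \code{unmatched_front} and \code{unmatched_top} (POSIXct vectors).
#' @export
matchByTimestamp <- function(front, top) {
  for (nm in c("front", "top")) {
    df <- get(nm)
    dup <- df$timestamp[duplicated(df$timestamp)]
    if (length(dup) > 0)
      stop("duplicate timestamp in ", nm, " view: ",
           formatFrameTimestamp(dup[1]))
  }
  common <- intersect(front$timestamp, top$timestamp)
  fi <- front[front$timestamp %in% common, , drop = FALSE]
  ti <- top[top$timestamp %in% common, , drop = FALSE]
  fi <- fi[order(fi$timestamp), , drop = FALSE]
  ti <- ti[order(ti$timestamp), , drop = FALSE]
  pairs <- data.frame(timestamp = fi$timestamp,
                      u_front = fi$u_px, v_front = fi$v_px,
                      status_front = fi$status,
                      u_top = ti$u_px, v_top = ti$v_px,
                      status_top = ti$status, stringsAsFactors = FALSE)
  list(pairs = pairs,
       unmatched_front = front$timestamp[!front$timestamp %in% common],
       unmatched_top = top$timestamp[!top$timestamp %in% common])
}

#' Fuse one matched detection pair into a 3D track point
#'
#' X is measured independently by both views; the fused X is their mean and
#' the absolute disagreement is recorded as \code{x_delta_mm}. Y comes from
#' the front view, Z from the top view. If either view is missing, the
#' previous point's coordinates are carried forward
#' (\code{source = "carried"}, contributing zero displacement); with no
#' previous point the pair is dropped (\code{NULL}).
#'
#' @param pair one row of \code{matchByTimestamp(...)$pairs}.
#' @param cal_front,cal_top [ViewCalibration] objects.
#' @param geom [TankGeometry].
#' @param previous previous track point (one-row data.frame) or
#'   \code{NULL}.
#' @param x_delta_warn_mm discrepancy above which a quality warning is
#'   attached (not a rejection).
#' @return One-row data.frame with \code{timestamp}, \code{x_mm},
#'   \code{y_mm}, \code{z_mm}, \code{x_delta_mm}, \code{source}; or
#'   \code{NULL}.
#' @export
fusePair <- function(pair, cal_front, cal_top, geom, previous = NULL,
                     x_delta_warn_mm = 50) {
  ok <- identical(pair$status_front, "detected") &&
        identical(pair$status_top, "detected")
  if (!ok) {
    if (is.null(previous)) return(NULL)
    out <- previous
    out$timestamp <- pair$timestamp
    out$source <- "carried"
    return(out)
  }
  mf <- pxToMm(cal_front, geom, pair$u_front, pair$v_front)
  mt <- pxToMm(cal_top, geom, pair$u_top, pair$v_top)
  xd <- abs(mf$x_mm - mt$x_mm)
  if (xd > x_delta_warn_mm)
    warning(sprintf("front/top X disagreement %.1f mm at %s", xd,
                    formatFrameTimestamp(pair$timestamp)))
  data.frame(timestamp = pair$timestamp,
             x_mm = (mf$x_mm + mt$x_mm) / 2, y_mm = mf$y_mm,
             z_mm = mt$z_mm, x_delta_mm = xd, source = "fused",
             stringsAsFactors = FALSE)
}

#' Fuse matched detections into a 3D track
#'
#' Applies [fusePair] along the matched pairs and assembles a [FishTrack]
#' with elapsed seconds \code{t_s} relative to the first retained point.
#'
#' @param matched result of [matchByTimestamp] (or its \code{pairs}
#'   data.frame).
#' @inheritParams fusePair
#' @return A [FishTrack].
#' @export
fuseTracks <- function(matched, cal_front, cal_top, geom,
                       x_delta_warn_mm = 50) {
  pairs <- if (is.data.frame(matched)) matched else matched$pairs
  pts <- vector("list", nrow(pairs))
  prev <- NULL
  for (i in seq_len(nrow(pairs))) {
    p <- fusePair(pairs[i, , drop = FALSE], cal_front, cal_top, geom,
                  prev, x_delta_warn_mm)
    pts[[i]] <- p
    if (!is.null(p)) prev <- p
  }
  pts <- pts[!vapply(pts, is.null, logical(1))]
  if (length(pts) == 0) {
    tr <- data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                     t_s = numeric(), x_mm = numeric(), y_mm = numeric(),
                     z_mm = numeric(), x_delta_mm = numeric(),
                     source = character(), stringsAsFactors = FALSE)
    return(FishTrack(tr, geom))
  }
  tr <- do.call(rbind, pts)
  tr$t_s <- as.numeric(difftime(tr$timestamp, tr$timestamp[1],
                                units = "secs"))
  tr <- tr[, c("timestamp", "t_s", "x_mm", "y_mm", "z_mm", "x_delta_mm",
               "source")]
  rownames(tr) <- NULL
  FishTrack(tr, geom)
}
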