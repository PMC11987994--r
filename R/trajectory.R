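#' Per-second swim speeds along a 3D track
#'
#' The speed at point i is the 3D Euclidean distance from point i-1 divided
#' by the elapsed time; the first point's speed is 0 by convention, so a
#' 1 Hz, 10-hour experiment yields 36,000 speed samples. Carried points
#' repeat the previous coordinates and therefore contribute zero speed.
#'
#' @param track a [FishTrack] or its track data.frame.
#' @return A data.frame with \code{t_s}, \code{speed_mm_s} and the nominal
#'   step \code{dt_s} as an attribute.
#' @examples
#' tr <- data.frame(timestamp = Sys.time() + 0:2, t_s = 0:2,
#'                  x_mm = c(0, 3, 3), y_mm = c(0, 4, 4), z_mm = 0,
#'                  x_delta_mm = 0, source = "fused")
#' stepSpeeds(tr)$speed_mm_s   # 0, 5, 0
#' @export
stepSpeeds <- function(track) {
  tr <- if (is(track, "FishTrack")) trackData(track) else track
  n <- nrow(tr)
  if (n == 0)
    return(structure(data.frame(t_s = numeric(), speed_mm_s = numeric()),
                     dt_s = 1))
  dt <- diff(tr$t_s)
  if (any(dt <= 0)) stop("t_s must be strictly increasing")
  d <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2 + diff(tr$z_mm)^2)
  structure(data.frame(t_s = tr$t_s,
                       speed_mm_s = c(0, d / dt)),
            dt_s = if (n > 1) stats::median(dt) else 1)
}

#' Total swim distance
#'
#' Sum of speed times step duration over the series; the cumulative
#' distance actually swum, in mm.
#'
#' @param series a speed series from [stepSpeeds] (or a [FishTrack]).
#' @return Total distance in mm (non-negative).
#' @export
totalDistance <- function(series) {
  if (is(series, "FishTrack")) series <- stepSpeeds(series)
  n <- nrow(series)
  if (n < 2) return(0)
  sum(series$speed_mm_s[-1] * diff(series$t_s))
}

#' Non-overlapping windowed speed means
#'
#' Averages the 1 Hz speeds over consecutive non-overlapping windows of
#' \code{window_s} seconds (default 10 s, the unit of the statistical
#' analysis); a trailing partial window is dropped, so a 36,000-sample
#' series yields exactly 3,600 means.
#'
#' @param series speed series from [stepSpeeds].
#' @param window_s window length in seconds; must be a positive multiple of
#'   the series' time step.
#' @return A data.frame with \code{window_index} (1-based) and
#'   \code{mean_speed_mm_s}; \code{window_s} is kept as an attribute.
#' @export
windowMeans <- function(series, window_s = 10) {
  if (is(series, "FishTrack")) series <- stepSpeeds(series)
  dt <- attr(series, "dt_s")
  if (is.null(dt)) dt <- if (nrow(series) > 1) stats::median(diff(series$t_s)) else 1
  per <- window_s / dt
  if (per <= 0 || abs(per - round(per)) > 1e-9)
    stop("window_s must be a positive multiple of the series time step")
  per <- round(per)
  k <- floor(nrow(series) / per)
  if (k == 0)
    return(structure(data.frame(window_index = integer(),
                                mean_speed_mm_s = numeric()),
                     window_s = window_s))
  x <- series$speed_mm_s[seq_len(k * per)]
  m <- colMeans(matrix(x, nrow = per))
  structure(data.frame(window_index = seq_len(k), mean_speed_mm_s = m),
            window_s = window_s)
}

#' 3D occupancy grid over a time slice
#'
#' Histograms the track positions falling in \code{[from_h, to_h)} hours
#' since track start into a regular 3D grid over the tank volume -- the
#' quantitative form of the intensity/trajectory plots used to describe
#' where the fish spent its time.
#'
#' @param track a [FishTrack].
#' @param slice_hours numeric(2) \code{c(from_h, to_h)}; defaults to the
#'   whole track.
#' @param bins_per_axis number of bins per axis (scalar or length 3 for
#'   X, Y, Z).
#' @return An \code{OccupancyGrid}: list with \code{counts} (3D array),
#'   \code{edges} (list of bin edges per axis, mm), \code{slice} (label)
#'   and \code{n} (points histogrammed).
#' @export
occupancy <- function(track, slice_hours = NULL, bins_per_axis = 10) {
  stopifnot(is(track, "FishTrack"))
  tr <- trackData(track)
  geom <- trackGeometry(track)
  if (is.null(slice_hours))
    slice_hours <- c(0, if (nrow(tr)) max(tr$t_s) / 3600 + 1e-9 else 0)
  sel <- tr$t_s >= slice_hours[1] * 3600 & tr$t_s < slice_hours[2] * 3600
  tr <- tr[sel, , drop = FALSE]
  nb <- rep_len(bins_per_axis, 3)
  edges <- list(x = seq(0, geom@width_mm, length.out = nb[1] + 1),
                y = seq(0, geom@water_mm, length.out = nb[2] + 1),
                z = seq(0, geom@depth_mm, length.out = nb[3] + 1))
  bin <- function(v, e) pmin(pmax(findInterval(v, e, all.inside = TRUE),
                                  1), length(e) - 1)
  counts <- array(0L, dim = nb)
  if (nrow(tr) > 0) {
    ix <- bin(tr$x_mm, edges$x)
    iy <- bin(tr$y_mm, edges$y)
    iz <- bin(tr$z_mm, edges$z)
    for (i in seq_len(nrow(tr)))
      counts[ix[i], iy[i], iz[i]] <- counts[ix[i], iy[i], iz[i]] + 1L
  }
  structure(list(counts = counts, edges = edges,
                 slice = sprintf("%g-%gh", slice_hours[1], slice_hours[2]),
                 n = nrow(tr)),
            class = "OccupancyGrid")
}

#' Long-format export of an occupancy grid
#'
#' @param grid an \code{OccupancyGrid} from [occupancy].
#' @return data.frame \code{x_bin, y_bin, z_bin, count, slice} (all bins,
#'   including empty ones).
#' @export
occupancyToLong <- function(grid) {
  d <- dim(grid$counts)
  out <- expand.grid(x_bin = seq_len(d[1]), y_bin = seq_len(d[2]),
                     z_bin = seq_len(d[3]))
  out$count <- as.vector(grid$counts)
  out$slice <- grid$slice
  out
}
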