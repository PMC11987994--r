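#' Read a pipeline run configuration
#'
#' Parses a YAML (or JSON) run configuration describing the tank geometry,
#' the two view calibrations, frame directories, detection parameters and
#' analysis settings. Missing detection parameters fall back to the
#' [DetectionParams] defaults.
#'
#' @param path YAML or JSON file. Expected blocks: \code{tank} (width_mm,
#'   depth_mm, height_mm, water_mm), \code{views$front} / \code{views$top}
#'   (dir, reference, roi as \code{[u0, v0, u1, v1]}, px_per_mm_u,
#'   px_per_mm_v, v_flip), optional \code{detection}, \code{window_s},
#'   \code{alpha}, \code{seed}, \code{out_dir}, \code{name_format}.
#' @return A \code{RunConfig} list: \code{geom}, \code{cal_front},
#'   \code{cal_top}, \code{paths}, \code{params}, \code{window_s},
#'   \code{alpha}, \code{seed}, \code{out_dir}, \code{name_format}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  tank <- cfg$tank
  geom <- TankGeometry(width_mm = tank$width_mm, depth_mm = tank$depth_mm,
                       height_mm = tank$height_mm,
                       water_mm = tank$water_mm)
  mkcal <- function(v, name) {
    ViewCalibration(view = name, roi = unlist(v$roi),
                    px_per_mm_u = v$px_per_mm_u,
                    px_per_mm_v = v$px_per_mm_v,
                    v_flip = isTRUE(v$v_flip))
  }
  det <- if (is.null(cfg$detection)) list() else cfg$detection
  params <- do.call(DetectionParams,
                    det[intersect(names(det),
                                  names(formals(DetectionParams)))])
  structure(list(
    geom = geom,
    cal_front = mkcal(cfg$views$front, "front"),
    cal_top = mkcal(cfg$views$top, "top"),
    paths = list(front_dir = cfg$views$front$dir,
                 top_dir = cfg$views$top$dir,
                 reference_front = cfg$views$front$reference,
                 reference_top = cfg$views$top$reference),
    params = params,
    window_s = if (is.null(cfg$window_s)) 10 else cfg$window_s,
    alpha = if (is.null(cfg$alpha)) 0.05 else cfg$alpha,
    seed = if (is.null(cfg$seed)) 1 else cfg$seed,
    out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir,
    name_format = if (is.null(cfg$name_format)) "%Y%m%d_%H%M%S"
                  else cfg$name_format), class = "RunConfig")
}

cfgLog <- function(cfg) file.path(cfg$out_dir, "run_log.jsonl")

#' Run per-view detection over the configured frame directories
#'
#' Streams both views' frame directories through the detection pipeline
#' and writes \code{detections_front.csv} and \code{detections_top.csv}
#' plus run-log records (frame counts, missing-detection rates).
#'
#' @param cfg a \code{RunConfig} from [readRunConfig].
#' @return Invisibly, a list with both detection data.frames.
#' @export
runTrack <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (vw in c("front", "top")) {
    cal <- cfg[[paste0("cal_", vw)]]
    t0 <- Sys.time()
    det <- trackDirectory(cfg$paths[[paste0(vw, "_dir")]],
                          cfg$paths[[paste0("reference_", vw)]],
                          cal, cfg$params, cfg$name_format)
    writeCsv(det, file.path(cfg$out_dir,
                            paste0("detections_", vw, ".csv")))
    logRunEvent(cfgLog(cfg), paste0("track_", vw),
                n_frames = nrow(det),
                n_missing = sum(det$status == "missing"),
                missing_rate = mean(det$status == "missing"),
                n_skipped = attr(det, "n_skipped"),
                elapsed_s = as.numeric(Sys.time() - t0, units = "secs"))
    out[[vw]] <- det
  }
  invisible(out)
}

#' Fuse detections and compute trajectory metrics
#'
#' Matches the two detection tables by timestamp, fuses them into a 3D
#' millimetre track, and writes \code{track.csv} (the fused track),
#' \code{speeds.csv} (\code{t_s, speed_mm_s, cum_dist_mm}),
#' \code{windows.csv} (\code{window_index, mean_speed_mm_s}) and a distance
#' summary to the run log.
#'
#' @param cfg a \code{RunConfig}.
#' @param detections optional list \code{(front, top)}; read back from the
#'   output CSVs when omitted.
#' @return Invisibly, a list with \code{track} ([FishTrack]),
#'   \code{speeds}, \code{windows} and \code{total_distance_mm}.
#' @export
runFuseMetrics <- function(cfg, detections = NULL) {
  if (is.null(detections)) {
    fp <- file.path(cfg$out_dir, "detections_front.csv")
    tp <- file.path(cfg$out_dir, "detections_top.csv")
    if (!file.exists(fp) || !file.exists(tp))
      stop("detections CSVs not found; run runTrack() first")
    detections <- list(front = readDetectionsCsv(fp),
                       top = readDetectionsCsv(tp))
  }
  matched <- matchByTimestamp(detections$front, detections$top)
  track <- fuseTracks(matched, cfg$cal_front, cfg$cal_top, cfg$geom)
  speeds <- stepSpeeds(track)
  wins <- windowMeans(speeds, cfg$window_s)
  dist <- totalDistance(speeds)
  tr <- trackData(track)
  writeCsv(tr, file.path(cfg$out_dir, "track.csv"))
  sp <- speeds
  sp$cum_dist_mm <- cumsum(sp$speed_mm_s *
                             c(0, diff(sp$t_s)))
  writeCsv(sp, file.path(cfg$out_dir, "speeds.csv"))
  writeCsv(wins, file.path(cfg$out_dir, "windows.csv"))
  logRunEvent(cfgLog(cfg), "fuse_metrics",
              n_points = nrow(tr),
              n_carried = sum(tr$source == "carried"),
              n_unmatched_front = length(matched$unmatched_front),
              n_unmatched_top = length(matched$unmatched_top),
              n_windows = nrow(wins),
              total_distance_mm = dist)
  invisible(list(track = track, speeds = speeds, windows = wins,
                 total_distance_mm = dist))
}

#' Run the statistical battery over group CSVs
#'
#' Reads one windowed-speed CSV per group (the \code{windows.csv} shape:
#' a \code{mean_speed_mm_s} column), runs [statsReport], and writes
#' \code{stats_descriptives.csv}, \code{stats_ks.csv},
#' \code{stats_pairwise.csv} (the Dunn-Bonferroni matrix) and
#' \code{stats_omnibus.csv}.
#'
#' @param cfg a \code{RunConfig}.
#' @param group_files named character vector of CSV paths (names are group
#'   labels), or a named list of numeric vectors.
#' @return Invisibly, the [statsReport] result.
#' @export
runStats <- function(cfg, group_files) {
  groups <- if (is.list(group_files) && is.numeric(group_files[[1]])) {
    group_files
  } else {
    lapply(group_files, function(f)
      utils::read.csv(f, stringsAsFactors = FALSE)$mean_speed_mm_s)
  }
  if (length(groups) < 2) stop("need at least 2 groups")
  rep <- statsReport(groups, cfg$alpha)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  writeCsv(rep$descriptives,
           file.path(cfg$out_dir, "stats_descriptives.csv"))
  writeCsv(rep$ks, file.path(cfg$out_dir, "stats_ks.csv"))
  pm <- as.data.frame(rep$pairwise$p.adjusted)
  pm <- cbind(group = rownames(pm), pm)
  writeCsv(pm, file.path(cfg$out_dir, "stats_pairwise.csv"))
  writeCsv(data.frame(H = rep$omnibus$H, df = rep$omnibus$df,
                      p.value = rep$omnibus$p.value,
                      significant = rep$omnibus_significant),
           file.path(cfg$out_dir, "stats_omnibus.csv"))
  logRunEvent(cfgLog(cfg), "stats", n_groups = length(groups),
              H = rep$omnibus$H, p = rep$omnibus$p.value)
  invisible(rep)
}

#' Occupancy exports and trajectory plots
#'
#' Splits the fused track into contiguous two-hour slices (plus the full
#' span), writes each occupancy grid as a long-format CSV, and draws the
#' front (X/Y) and top (X/Z) trajectory projections coloured from green
#' (early) to red (late) as PNGs.
#'
#' @param cfg a \code{RunConfig}.
#' @param track optional [FishTrack]; read back from \code{track.csv} when
#'   omitted.
#' @param slice_h slice length in hours.
#' @param bins_per_axis occupancy bins per axis.
#' @return Invisibly, the list of occupancy grids.
#' @export
runReport <- function(cfg, track = NULL, slice_h = 2, bins_per_axis = 10) {
  if (is.null(track)) {
    tp <- file.path(cfg$out_dir, "track.csv")
    if (!file.exists(tp)) stop("track.csv not found; run fuse first")
    tr <- readDetectionsCsv(tp)
    track <- FishTrack(tr, cfg$geom)
  }
  tr <- trackData(track)
  span_h <- if (nrow(tr)) max(tr$t_s) / 3600 else 0
  starts <- seq(0, span_h, by = slice_h)
  starts <- starts[starts < span_h | length(starts) == 1]
  slices <- lapply(starts, function(s) c(s, s + slice_h))
  slices <- c(slices, list(c(0, span_h + 1e-9)))
  grids <- list()
  for (sl in slices) {
    g <- occupancy(track, sl, bins_per_axis)
    writeCsv(occupancyToLong(g),
             file.path(cfg$out_dir,
                       sprintf("occupancy_%s.csv", g$slice)))
    grids[[g$slice]] <- g
  }
  plotTrackProjections(track, file.path(cfg$out_dir, "track_views.png"))
  logRunEvent(cfgLog(cfg), "report", n_slices = length(grids),
              n_points = nrow(tr))
  invisible(grids)
}

#' Plot front/top trajectory projections coloured by time
#'
#' @param track a [FishTrack].
#' @param file output PNG path.
#' @return \code{file}, invisibly.
#' @export
plotTrackProjections <- function(track, file) {
  tr <- trackData(track)
  geom <- trackGeometry(track)
  cols <- grDevices::colorRampPalette(c("green3", "orange", "red"))(100)
  ci <- if (nrow(tr) > 1)
    1 + floor(99 * (tr$t_s - min(tr$t_s)) /
                max(max(tr$t_s) - min(tr$t_s), 1))
  else rep(1, nrow(tr))
  grDevices::png(file, width = 1200, height = 500)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot(tr$x_mm, tr$y_mm, col = cols[ci], pch = 16, cex = 0.5,
                 xlim = c(0, geom@width_mm), ylim = c(0, geom@water_mm),
                 xlab = "X (mm)", ylab = "Y (mm)",
                 main = "Front view (green = early, red = late)")
  graphics::plot(tr$x_mm, tr$z_mm, col = cols[ci], pch = 16, cex = 0.5,
                 xlim = c(0, geom@width_mm), ylim = c(0, geom@depth_mm),
                 xlab = "X (mm)", ylab = "Z (mm)", main = "Top view")
  invisible(file)
}

#' Simulate, render and write a complete synthetic experiment
#'
#' Convenience wrapper for the command line: simulates a trajectory,
#' renders both views to \code{out_dir} and returns the render manifest.
#'
#' @param motion a [MotionConfig].
#' @param scene a [SceneConfig].
#' @param geom a [TankGeometry].
#' @param out_dir output directory.
#' @return The [renderViews] manifest (file paths and ground truth).
#' @export
runSimulate <- function(motion, scene, geom = TankGeometry(), out_dir) {
  gt <- simulateTrajectory(motion, geom)
  res <- renderViews(gt, scene, out_dir)
  logRunEvent(file.path(out_dir, "run_log.jsonl"), "simulate",
              n_frames = nrow(gt$positions),
              distance_mm = gt$distance_mm)
  res
}
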