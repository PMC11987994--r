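#' Parse frame timestamps from filenames
#'
#' @param x character vector of timestamp stems (no extension).
#' @param format \code{\link{strptime}} pattern, default
#'   \code{YYYYMMDD_HHMMSS}.
#' @return POSIXct (UTC); NA where unparseable.
#' @export
parseFrameTimestamp <- function(x, format = "%Y%m%d_%H%M%S") {
  as.POSIXct(x, format = format, tz = "UTC")
}

#' @rdname parseFrameTimestamp
#' @param t POSIXct vector.
#' @export
formatFrameTimestamp <- function(t, format = "%Y%m%d_%H%M%S") {
  format(t, format = format, tz = "UTC")
}

#' Read a PNG frame as an intensity matrix
#'
#' Reads a PNG and returns intensities in [0, 255]; colour images are
#' converted to luminance.
#'
#' @param path PNG file path.
#' @return Grayscale matrix (rows = image v, columns = u).
#' @export
readImagePixels <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    px <- px[, , seq_len(min(3, dim(px)[3])), drop = FALSE]
    if (dim(px)[3] == 3)
      px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    else px <- px[, , 1]
  }
  px * 255
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' @param px matrix in [0, 255].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeImagePixels <- function(px, path) {
  px <- pmin(pmax(px, 0), 255)
  png::writePNG(round(px) / 255, path)
  invisible(path)
}

#' Append a JSON-lines record to a run log
#'
#' Every pipeline command writes machine-readable progress records (stage,
#' counts, timings) to \code{run_log.jsonl} in its output directory.
#'
#' @param .logfile log file path.
#' @param .stage character stage label.
#' @param ... further scalar fields to record.
#' @return Invisibly, the record as a list.
#' @export
logRunEvent <- function(.logfile, .stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z",
                              tz = "UTC"),
                stage = .stage), list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = .logfile, append = TRUE)
  invisible(rec)
}

# CSV conventions fixed for reproducibility: comma-separated, UTF-8,
# '.' decimal, header row, no row names.
writeCsv <- function(df, path) {
  if ("timestamp" %in% names(df) && inherits(df$timestamp, "POSIXct"))
    df$timestamp <- formatFrameTimestamp(df$timestamp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

readDetectionsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$timestamp <- parseFrameTimestamp(df$timestamp)
  df
}
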