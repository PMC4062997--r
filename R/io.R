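#' Write a frame sequence as a PNG directory with a JSON manifest
#'
#' @param seq A `frame_sequence`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frame_sequence <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(seq$frames)
  width <- max(5L, nchar(as.character(n)))
  for (i in seq_len(n)) {
    png::writePNG(pmin(pmax(seq$frames[[i]], 0), 1),
                  file.path(dir, sprintf("frame_%0*d.png", width, i)))
  }
  jsonlite::write_json(list(fps = seq$fps, width = seq$width,
                            height = seq$height, n_frames = n),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a frame sequence from a PNG directory
#'
#' @param dir Directory written by [write_frame_sequence()] (PNG frames in
#'   lexical order plus `manifest.json`).
#' @return A `frame_sequence`.
#' @export
read_frame_sequence <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  })
  structure(list(frames = frames, fps = man$fps, width = man$width,
                 height = man$height), class = "frame_sequence")
}

#' Write an accelerometer trace as CSV (`t,x,y,z`)
#' @param trace An [accel_trace()].
#' @param path Output file.
#' @export
write_accel_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("t", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an accelerometer trace from CSV (`t,x,y,z`)
#' @param path CSV file with header `t,x,y,z` (seconds, g).
#' @param fs Nominal sampling rate; estimated from timestamps when missing.
#' @export
read_accel_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$t))
  accel_trace(df$t, df$x, df$y, df$z, fs = fs)
}

#' Write a time-angle matrix as CSV (columns B1..B8, one row per flow step)
#' @param tam A `time_angle_matrix`.
#' @param path Output file.
#' @export
write_time_angle_csv <- function(tam, path) {
  df <- as.data.frame(t(unclass(tam)))
  df <- cbind(step = seq_len(nrow(df)), time = attr(tam, "times"), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a behavioral record as nested JSON
#' @param record A [behavioral_record()].
#' @param path Output file.
#' @export
write_record_json <- function(record, path) {
  outer <- lapply(record$outer, function(o) {
    list(zone = o$zone, entered = o$entered,
         inner = lapply(o$inner, function(i)
           list(timestamp = i$timestamp,
                state = as.list(stats::setNames(as.numeric(i$state),
                                                pose_classes())),
                candidates = i$candidates,
                raw_ref = i$raw_ref)))
  })
  jsonlite::write_json(list(zones = record$zones, outer = outer), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
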