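#' Write / read a recording on disk
#'
#' Binary format: little-endian 32-bit float samples, channel-major
#' (channel 1's samples, then channel 2's, ...), with a JSON sidecar
#' `<prefix>.json` holding `sampling_rate`, `channels`, `t0` and
#' `n_samples`. Text format: single channel only, two tab-separated
#' columns `time_s`, `value`.
#'
#' @param rec a [recording()].
#' @param prefix file path without extension; binary writes
#'   `<prefix>.f32` + `<prefix>.json`, text writes `<prefix>.tsv`.
#' @param format `"binary"` or `"text"`.
#' @return the main file path, invisibly.
#' @export
write_recording <- function(rec, prefix, format = c("binary", "text")) {
  format <- match.arg(format)
  if (format == "binary") {
    path <- paste0(prefix, ".f32")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(rec$samples), con, size = 4, endian = "little")
    jsonlite::write_json(
      list(sampling_rate = rec$sampling_rate,
           channels = rec$channel_labels, t0 = rec$t0,
           n_samples = nrow(rec$samples)),
      paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    if (ncol(rec$samples) != 1)
      stop("text format supports a single channel")
    path <- paste0(prefix, ".tsv")
    utils::write.table(
      data.frame(time_s = rec_times(rec), value = rec$samples[, 1]),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix, format = c("binary", "text")) {
  format <- match.arg(format)
  if (format == "binary") {
    meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
    con <- file(paste0(prefix, ".f32"), "rb")
    on.exit(close(con))
    n <- meta$n_samples * length(meta$channels)
    x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
    recording(matrix(x, ncol = length(meta$channels)),
              meta$sampling_rate, meta$channels, meta$t0)
  } else {
    d <- utils::read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t")
    fs <- 1 / stats::median(diff(d$time_s))
    recording(d$value, fs, t0 = d$time_s[1])
  }
}

#' Write / read ground truth or onset tables as JSON
#'
#' @param truth ground-truth list from [generate_lfp()], or any
#'   JSON-serializable list / data.frame (e.g. an onset table).
#' @param path file path.
#' @return `path` invisibly / the parsed object.
#' @export
write_truth <- function(truth, path) {
  if (!is.null(truth$seizure_intervals))
    truth$seizure_intervals <- as.data.frame(truth$seizure_intervals)
  if (!is.null(truth$light_intervals))
    truth$light_intervals <- as.data.frame(truth$light_intervals)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(tr$seizure_intervals))
    tr$seizure_intervals <- as.matrix(tr$seizure_intervals)
  if (!is.null(tr$light_intervals))
    tr$light_intervals <- as.matrix(tr$light_intervals)
  tr
}

#' Write calcium traces as a delimited matrix with a frame-time column
#'
#' @param traces cells x frames matrix.
#' @param frame_times s.
#' @param path file path (CSV).
#' @return `path` invisibly.
#' @export
write_traces <- function(traces, frame_times, path) {
  d <- data.frame(frame_time_s = frame_times, t(traces))
  utils::write.table(d, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = ",")
  list(traces = t(as.matrix(d[, -1, drop = FALSE])),
       frame_times = d$frame_time_s)
}

#' Write a calcium movie and its masks as TIFF
#'
#' Multi-page 32-bit float TIFF for the movie (values are rescaled to
#' [0, 1] as the format requires; the scale and offset are stored in a
#' JSON sidecar and undone on read) and a 16-bit labeled TIFF for the
#' masks. Requires the `tiff` package.
#'
#' @param movie frames x rows x cols array.
#' @param masks integer label matrix.
#' @param prefix path prefix; writes `<prefix>_movie.tif`,
#'   `<prefix>_masks.tif`, `<prefix>_movie.json`.
#' @return `prefix` invisibly.
#' @export
write_movie <- function(movie, masks, prefix) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for movie output")
  lo <- min(movie); hi <- max(movie)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(movie)[1]), function(f)
    (movie[f, , ] - lo) / scale)
  tiff::writeTIFF(pages, paste0(prefix, "_movie.tif"), bits.per.sample = 32)
  tiff::writeTIFF(masks / 65535, paste0(prefix, "_masks.tif"),
                  bits.per.sample = 16)
  jsonlite::write_json(list(offset = lo, scale = scale),
                       paste0(prefix, "_movie.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_movie
#' @export
read_movie <- function(prefix) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for movie input")
  meta <- jsonlite::read_json(paste0(prefix, "_movie.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, "_movie.tif"), all = TRUE)
  movie <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages))
    movie[f, , ] <- pages[[f]] * meta$scale + meta$offset
  masks <- round(tiff::readTIFF(paste0(prefix, "_masks.tif")) * 65535)
  storage.mode(masks) <- "integer"
  list(movie = movie, masks = masks)
}
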