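#' Uniformly sampled multichannel recording
#'
#' Container for continuous electrophysiology: a numeric matrix with one
#' column per channel, a sampling rate in Hz, channel labels and a start
#' time. Sample `i` (1-based) of any channel occurs at
#' `t0 + (i - 1) / sampling_rate` seconds.
#'
#' @param samples numeric vector (single channel) or matrix with one column
#'   per channel, in signal units.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per channel.
#' @param t0 time of the first sample in seconds (default 0).
#'
#' @return An object of class `"recording"`: a list with elements
#'   `samples` (matrix, samples x channels), `sampling_rate`,
#'   `channel_labels`, `t0`.
#' @export
#' @examples
#' rec <- recording(sin(2 * pi * 5 * seq(0, 1, by = 1 / 500)), 500)
#' rec_duration(rec)
recording <- function(samples, sampling_rate, channel_labels = NULL, t0 = 0) {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  if (!is.matrix(samples)) stop("'samples' must be a vector or matrix")
  stopifnot_scalar(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) stop("'sampling_rate' must be > 0")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_labels) != ncol(samples))
    stop("one channel label per column required")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         channel_labels = as.character(channel_labels), t0 = t0),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$sampling_rate,
              rec_duration(x)))
  cat(" channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration, times and channel access for recordings
#'
#' @param rec a [recording()].
#' @return `rec_duration`: length in seconds; `rec_times`: vector of sample
#'   times in seconds; `rec_channel`: one channel as a numeric vector.
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$sampling_rate

#' @rdname rec_duration
#' @export
rec_times <- function(rec) {
  rec$t0 + (seq_len(nrow(rec$samples)) - 1) / rec$sampling_rate
}

#' @rdname rec_duration
#' @param channel channel index or label.
#' @export
rec_channel <- function(rec, channel = 1L) {
  if (is.character(channel)) channel <- match(channel, rec$channel_labels)
  if (is.na(channel) || channel < 1L || channel > ncol(rec$samples))
    stop("unknown channel")
  rec$samples[, channel]
}

# index of the sample nearest to time t (1-based, clipped to the record)
time_to_index <- function(rec, t) {
  i <- round((t - rec$t0) * rec$sampling_rate) + 1
  pmin(pmax(i, 1L), nrow(rec$samples))
}
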