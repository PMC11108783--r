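#' Extract ROI fluorescence traces from a movie
#'
#' For each labeled region of interest, the trace value at a frame is the
#' mean of the movie over the ROI's pixels in that frame (extraction is
#' therefore linear in the movie).
#'
#' @param movie frames x rows x cols numeric array.
#' @param masks integer rows x cols label matrix (0 = background, k = ROI
#'   k), as produced by [render_calcium_movie()].
#' @return cells x frames matrix of raw traces.
#' @export
extract_traces <- function(movie, masks) {
  labels <- sort(setdiff(unique(as.vector(masks)), 0L))
  if (length(labels) == 0) stop("mask contains no ROI")
  n_frames <- dim(movie)[1]
  flat <- matrix(movie, nrow = n_frames)     # frames x (rows*cols)
  out <- matrix(0, nrow = length(labels), ncol = n_frames)
  for (i in seq_along(labels)) {
    pix <- which(as.vector(masks) == labels[i])
    if (length(pix) == 0) stop("empty ROI mask")
    out[i, ] <- rowMeans(flat[, pix, drop = FALSE])
  }
  rownames(out) <- paste0("cell", labels)
  out
}

#' Fractional fluorescence change (dF/F)
#'
#' Baseline F0 is a rolling 8th-percentile of the raw trace over a 30 s
#' centred window (shrunken at the record edges), and
#' dF/F = (F - F0) / F0. The ratio is invariant to a global multiplicative
#' gain on F. Percentile and window are configurable.
#'
#' @param trace numeric raw fluorescence vector (one cell).
#' @param frame_times frame times, s.
#' @param baseline_percentile percentile in (0, 100) used for F0.
#' @param baseline_window window length, s.
#' @return list `(dff, baseline, frame_times)`.
#' @export
compute_dff <- function(trace, frame_times, baseline_percentile = 8,
                        baseline_window = 30) {
  n <- length(trace)
  if (n != length(frame_times)) stop("trace/frame_times length mismatch")
  dt <- stats::median(diff(frame_times))
  half <- max(1L, round(baseline_window / 2 / dt))
  f0 <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::quantile(trace[lo:hi], baseline_percentile / 100, names = FALSE)
  }, 0)
  if (any(f0 <= 0))
    stop("nonpositive baseline; dF/F undefined (offset the trace first)")
  list(dff = (trace - f0) / f0, baseline = f0, frame_times = frame_times)
}

#' Normalize a dF/F trace to its maximum
#'
#' Divides by the cell's maximum so the new maximum is exactly 1. A
#' monotone transform: ordering of time points is preserved, and the
#' operation is idempotent. Cells whose maximum is not positive cannot be
#' normalized and are rejected with a warning (return NULL).
#'
#' @param dff numeric dF/F vector.
#' @return normalized vector, or NULL when max(dff) <= 0.
#' @export
normalize_to_max <- function(dff) {
  m <- max(dff)
  if (!is.finite(m) || m <= 0) {
    warning("cell maximum <= 0; cell dropped from normalization")
    return(NULL)
  }
  dff / m
}

#' Event-aligned peri-event matrix
#'
#' Averages each cell's max-normalized dF/F across events on a common
#' relative-time grid: bin centres run from `-pre` to `+post` in steps of
#' `bin`, each bin takes the frame nearest its centre (bit-reproducible),
#' and events whose window extends beyond the recording contribute only
#' their in-range bins (per-bin event counts are tracked).
#'
#' @param dff cells x frames matrix of (normalized) dF/F.
#' @param frame_times s.
#' @param event_times s (time 0 of the alignment).
#' @param pre,post window extent before/after the event, s.
#' @param bin bin width, s (default one frame period).
#' @param sort_rows order rows by time of peak (cosmetic, default FALSE).
#' @return list of class `"peri_event_matrix"`: `values` (cells x bins),
#'   `bin_centers` (s, 0 = event), `n_events` (per-bin usable event
#'   counts), `event_times`.
#' @export
align_to_events <- function(dff, frame_times, event_times, pre = 5, post = 5,
                            bin = NULL, sort_rows = FALSE) {
  if (is.vector(dff)) dff <- matrix(dff, nrow = 1)
  bin <- bin %||% stats::median(diff(frame_times))
  centers <- seq(-pre, post, by = bin)
  t_end <- frame_times[length(frame_times)]
  usable <- event_times[event_times >= frame_times[1] &
                        event_times <= t_end]
  if (length(usable) == 0) stop("no usable events inside the recording")
  n_cells <- nrow(dff)
  acc <- matrix(0, n_cells, length(centers))
  cnt <- integer(length(centers))
  for (ev in usable) {
    tt <- ev + centers
    ok <- tt >= frame_times[1] & tt <= t_end
    idx <- vapply(tt[ok], function(t) which.min(abs(frame_times - t)), 1L)
    acc[, ok] <- acc[, ok] + dff[, idx, drop = FALSE]
    cnt[ok] <- cnt[ok] + 1L
  }
  if (any(cnt == 0)) warning("some bins received no events")
  vals <- sweep(acc, 2, pmax(cnt, 1L), "/")
  if (sort_rows && n_cells > 1) {
    pk <- apply(vals, 1, which.max)
    vals <- vals[order(pk), , drop = FALSE]
  }
  structure(list(values = vals, bin_centers = centers, n_events = cnt,
                 event_times = usable),
            class = "peri_event_matrix")
}

#' Correlation between calcium activity and spiking
#'
#' The spike train is binned into a rate signal (default bin = one frame
#' period), linearly interpolated onto the frame times, and each cell's
#' dF/F is correlated with it (product-moment). Cells with zero variance
#' on either side are excluded. The summary is the mean +/- s.e.m. of r
#' across cells.
#'
#' @param dff cells x frames matrix.
#' @param frame_times s.
#' @param spike_times s.
#' @param rate_bin bin width for the rate signal, s.
#' @return list `(r, mean_r, sem_r, n_cells)`; `r` has one entry per cell
#'   (NA where undefined).
#' @export
activity_spiking_correlation <- function(dff, frame_times, spike_times,
                                         rate_bin = NULL) {
  if (is.vector(dff)) dff <- matrix(dff, nrow = 1)
  rate_bin <- rate_bin %||% stats::median(diff(frame_times))
  t0 <- frame_times[1]; t1 <- frame_times[length(frame_times)]
  breaks <- seq(t0, t1 + rate_bin, by = rate_bin)
  sp <- spike_times[spike_times >= t0 & spike_times <= t1]
  counts <- tabulate(findInterval(sp, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  rate <- counts / rate_bin
  mids <- head(breaks, -1) + rate_bin / 2
  rate_f <- stats::approx(mids, rate, xout = frame_times, rule = 2)$y
  r <- apply(dff, 1, function(v) {
    if (stats::sd(v) == 0 || stats::sd(rate_f) == 0) return(NA_real_)
    stats::cor(v, rate_f)
  })
  ok <- r[!is.na(r)]
  list(r = r, mean_r = mean(ok),
       sem_r = if (length(ok) > 1) stats::sd(ok) / sqrt(length(ok)) else NA_real_,
       n_cells = length(ok))
}
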