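#' Spike detection criteria
#'
#' The detector is criterion-based: a band-pass filter, an amplitude
#' threshold in robust-SD units, width (full width at half maximum)
#' bounds, and normalized template matching, each producing a per-event
#' flag that a Boolean rule then combines. All values are experimenter
#' inputs; the defaults here are documented starting points, not claims
#' about any particular preparation.
#'
#' @param band c(low, high) pass band, Hz.
#' @param filter_order Butterworth order.
#' @param threshold amplitude threshold, multiples of the robust SD
#'   (1.4826 x median absolute deviation) of the filtered channel.
#' @param polarity "negative", "positive" or "both" (absolute value).
#' @param width_bounds c(min, max) acceptable FWHM, s.
#' @param template numeric waveform vector used for matching (NULL
#'   disables the template flag); `template_min_score` is the minimum
#'   normalized cross-correlation in [-1, 1].
#' @param template_min_score see `template`.
#' @param refractory minimum separation between accepted candidates, s.
#' @param measure_window window around a candidate used for amplitude /
#'   width measurement, s.
#' @return list of class `"spike_criteria"`.
#' @export
spike_criteria <- function(band = c(5, 40), filter_order = 4, threshold = 5,
                           polarity = c("negative", "positive", "both"),
                           width_bounds = c(0.010, 0.080),
                           template = NULL, template_min_score = 0.6,
                           refractory = 0.1, measure_window = 0.12) {
  polarity <- match.arg(polarity)
  if (band[1] <= 0 || band[2] <= band[1]) stop("invalid band")
  if (width_bounds[1] >= width_bounds[2]) stop("invalid width bounds")
  if (refractory < 0) stop("refractory must be >= 0")
  structure(list(band = band, filter_order = filter_order,
                 threshold = threshold, polarity = polarity,
                 width_bounds = width_bounds, template = template,
                 template_min_score = template_min_score,
                 refractory = refractory, measure_window = measure_window),
            class = "spike_criteria")
}

#' Artifact rejection criteria
#'
#' An event is vetoed when it lies within `veto_pad` seconds (closed
#' boundary) of a saturated sample or of a window whose broadband power
#' exceeds `broadband_threshold` robust SDs of the session's broadband
#' envelope.
#'
#' @param saturation_level absolute signal level treated as clipping.
#' @param broadband_band c(low, high) Hz band used for the broadband
#'   power veto; NULL disables it.
#' @param broadband_threshold robust-SD multiples.
#' @param broadband_window window length for broadband power, s.
#' @param veto_pad half-width of the veto around an artifact, s.
#' @return list of class `"artifact_criteria"`.
#' @export
artifact_criteria <- function(saturation_level = Inf,
                              broadband_band = NULL,
                              broadband_threshold = 5,
                              broadband_window = 0.2,
                              veto_pad = 0.5) {
  if (veto_pad < 0) stop("veto_pad must be >= 0")
  structure(list(saturation_level = saturation_level,
                 broadband_band = broadband_band,
                 broadband_threshold = broadband_threshold,
                 broadband_window = broadband_window,
                 veto_pad = veto_pad),
            class = "artifact_criteria")
}

butter_coefs <- function(band, order, fs) {
  nyq <- fs / 2
  if (band[2] >= nyq) stop("band edge at or above Nyquist frequency")
  signal::butter(order, band / nyq, type = "pass")
}

#' Zero-phase band-pass filter a recording
#'
#' Forward-backward Butterworth filtering of every channel; length is
#' preserved and phase is zero (offline use — the streaming detector uses
#' the causal variant of the same filter).
#'
#' @param rec a [recording()].
#' @param band c(low, high) Hz.
#' @param order Butterworth order (default 4).
#' @return A filtered [recording()].
#' @export
bandpass_filter <- function(rec, band, order = 4) {
  bf <- butter_coefs(band, order, rec$sampling_rate)
  out <- apply(rec$samples, 2, function(x) signal::filtfilt(bf, x))
  recording(out, rec$sampling_rate, rec$channel_labels, rec$t0)
}

#' Detect threshold crossings on a filtered channel
#'
#' The threshold is `threshold` times the robust SD (1.4826 x MAD) of the
#' filtered channel, so detection is invariant to signal scaling and the
#' threshold is not inflated by seizure-dense records. Each supra-threshold
#' excursion yields one candidate at its extremum; candidates closer than
#' `refractory` to the previously accepted candidate are suppressed
#' (earlier wins; coincident candidates resolve to the earlier time, then
#' the larger amplitude).
#'
#' @param rec filtered single-channel [recording()].
#' @param threshold robust-SD multiples.
#' @param polarity "negative", "positive" or "both".
#' @param refractory s.
#' @return data.frame `(time, amplitude)`, one row per candidate;
#'   zero-variance input yields an empty frame.
#' @export
detect_threshold_crossings <- function(rec, threshold = 5,
                                       polarity = "negative",
                                       refractory = 0.1) {
  x <- rec_channel(rec, 1L)
  sdr <- robust_sd(x)
  if (!is.finite(sdr) || sdr == 0)
    return(data.frame(time = numeric(0), amplitude = numeric(0)))
  s <- switch(polarity, negative = -x, positive = x, both = abs(x),
              stop("unknown polarity"))
  thr <- threshold * sdr
  cand <- excursion_extrema(s, thr)
  if (nrow(cand) == 0)
    return(data.frame(time = numeric(0), amplitude = numeric(0)))
  times <- rec$t0 + (cand$index - 1) / rec$sampling_rate
  amps <- cand$value
  keep <- apply_refractory(times, refractory)
  data.frame(time = times[keep], amplitude = amps[keep])
}

# one extremum per contiguous run of s > thr; vectorized
excursion_extrema <- function(s, thr) {
  above <- s > thr
  if (!any(above)) return(data.frame(index = integer(0), value = numeric(0)))
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L); ends <- which(d == -1L) - 1L
  idx <- mapply(function(a, b) a - 1L + which.max(s[a:b]), starts, ends)
  data.frame(index = as.integer(idx), value = s[idx])
}

# earliest-wins refractory suppression on sorted times
apply_refractory <- function(times, refractory) {
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) { keep[i] <- TRUE; last <- times[i] }
  }
  keep
}

#' Measure amplitude and width of a spike candidate
#'
#' Amplitude is the extremum magnitude inside the window around the
#' candidate; width is the full width at half maximum — the time the
#' excursion stays beyond half its extremum, contiguous around it.
#' Windows are clipped at the record edges.
#'
#' @param rec filtered single-channel [recording()].
#' @param time candidate time, s.
#' @param window half-width of the measurement window, s.
#' @param polarity as in [detect_threshold_crossings()].
#' @return list `(amplitude, width)`; a flat window reports both as 0.
#' @export
measure_spike <- function(rec, time, window = 0.06, polarity = "negative") {
  measure_spike_vec(rec_channel(rec, 1L), rec$sampling_rate, rec$t0,
                    time, window, polarity)
}

measure_spike_vec <- function(x, fs, t0, time, window, polarity) {
  ctr <- round((time - t0) * fs) + 1
  i0 <- max(1L, ctr - round(window * fs))
  i1 <- min(length(x), ctr + round(window * fs))
  seg <- x[i0:i1]
  s <- switch(polarity, negative = -seg, positive = seg, both = abs(seg))
  pk <- which.max(s)
  amp <- s[pk]
  if (!is.finite(amp) || amp <= 0) return(list(amplitude = 0, width = 0))
  half <- amp / 2
  above <- s >= half
  # contiguous run containing the extremum
  a <- pk; while (a > 1L && above[a - 1L]) a <- a - 1L
  b <- pk; while (b < length(s) && above[b + 1L]) b <- b + 1L
  list(amplitude = amp, width = (b - a + 1L) / fs)
}

#' Normalized template match at a candidate
#'
#' Zero-mean, unit-norm cross-correlation between the template and the
#' candidate-centred window. The shift within +/- `jitter` seconds with
#' the largest correlation magnitude is selected and its signed score
#' returned, so a perfect match scores 1 and a perfect sign inversion -1.
#' Scores lie in [-1, 1]; a zero-variance window scores 0.
#'
#' @param rec filtered single-channel [recording()].
#' @param time candidate time, s.
#' @param template numeric waveform vector (same sampling rate as `rec`).
#' @param jitter maximum shift examined, s (default 0.005).
#' @return best score, numeric scalar.
#' @export
template_match <- function(rec, time, template, jitter = 0.005) {
  template_match_vec(rec_channel(rec, 1L), rec$sampling_rate, rec$t0,
                     time, template, jitter)
}

template_match_vec <- function(x, fs, t0, time, template, jitter = 0.005) {
  m <- length(template)
  if (m >= length(x)) stop("template longer than recording")
  tz <- template - mean(template)
  tn <- sqrt(sum(tz^2))
  if (tn == 0) return(0)
  tz <- tz / tn
  centre <- min(max(round((time - t0) * fs) + 1, 1L), length(x))
  shifts <- -round(jitter * fs):round(jitter * fs)
  # align template extremum with the candidate
  peak_off <- which.max(abs(template)) - 1L
  best <- 0
  for (sh in shifts) {
    i0 <- centre - peak_off + sh
    idx <- i0:(i0 + m - 1L)
    if (idx[1] < 1L || idx[m] > length(x)) next
    w <- x[idx]
    wz <- w - mean(w)
    wn <- sqrt(sum(wz^2))
    score <- if (wn == 0) 0 else sum(wz * tz) / wn
    if (abs(score) > abs(best)) best <- score
  }
  best
}

#' Flag events near artifacts
#'
#' An event is artifact-flagged when it lies within `veto_pad` seconds
#' (closed boundary: exactly `veto_pad` away is still flagged) of a
#' saturated sample (|x| >= `saturation_level`) or of a window whose
#' broadband-band envelope power exceeds the threshold.
#'
#' @param rec raw single-channel [recording()].
#' @param events data.frame with a `time` column.
#' @param criteria an [artifact_criteria()].
#' @return `events` with a logical `artifact` column added.
#' @export
reject_artifacts <- function(rec, events, criteria) {
  x <- rec_channel(rec, 1L)
  fs <- rec$sampling_rate
  art_times <- numeric(0)
  if (is.finite(criteria$saturation_level)) {
    sat <- which(abs(x) >= criteria$saturation_level)
    if (length(sat) > 0)
      art_times <- c(art_times, rec$t0 + (sat - 1) / fs)
  }
  if (!is.null(criteria$broadband_band)) {
    bf <- butter_coefs(criteria$broadband_band, 4, fs)
    xb <- signal::filtfilt(bf, x)
    wlen <- max(1L, round(criteria$broadband_window * fs))
    nwin <- floor(length(xb) / wlen)
    if (nwin > 0) {
      pw <- vapply(seq_len(nwin), function(k)
        sqrt(mean(xb[((k - 1) * wlen + 1):(k * wlen)]^2)), 0)
      thr <- criteria$broadband_threshold * robust_sd(pw) + stats::median(pw)
      bad <- which(pw > thr)
      if (length(bad) > 0)
        art_times <- c(art_times,
                       rec$t0 + (bad - 0.5) * criteria$broadband_window)
    }
  }
  if (length(art_times) == 0 || nrow(events) == 0) {
    events$artifact <- rep(FALSE, nrow(events))
    return(events)
  }
  events$artifact <- vapply(events$time, function(t)
    any(abs(t - art_times) <= criteria$veto_pad), TRUE)
  events
}

#' Combine per-criterion flags with a Boolean rule
#'
#' The rule is an expression over flag names using AND / OR / NOT and
#' parentheses, e.g. `"((amplitude AND width) OR template) AND NOT artifact"`.
#' Evaluation is pure and order-independent: an event is accepted exactly
#' when its flag assignment satisfies the expression.
#'
#' @param events data.frame with one logical column per flag named in the
#'   rule.
#' @param rule character rule string.
#' @return the accepted subset of `events`.
#' @export
#' @examples
#' ev <- data.frame(time = 1:4, amplitude = c(TRUE, TRUE, FALSE, FALSE),
#'                  artifact = c(FALSE, TRUE, FALSE, TRUE))
#' combine_criteria(ev, "amplitude AND NOT artifact")
combine_criteria <- function(events, rule) {
  expr <- parse_bool_rule(rule)
  vars <- all.vars(expr)
  missing_v <- setdiff(vars, names(events))
  if (length(missing_v) > 0)
    stop("rule references undefined flags: ", paste(missing_v, collapse = ", "))
  for (v in vars) if (!is.logical(events[[v]]))
    stop(sprintf("flag '%s' is not logical", v))
  keep <- eval(expr, envir = events, enclos = baseenv())
  events[keep, , drop = FALSE]
}

parse_bool_rule <- function(rule) {
  s <- rule
  s <- gsub("\\bAND\\b", "&", s, ignore.case = TRUE)
  s <- gsub("\\bOR\\b", "|", s, ignore.case = TRUE)
  s <- gsub("\\bNOT\\b", "!", s, ignore.case = TRUE)
  ex <- tryCatch(parse(text = s)[[1]],
                 error = function(e) stop("cannot parse rule: ", rule,
                                          call. = FALSE))
  check_bool_ast(ex)
  ex
}

check_bool_ast <- function(ex) {
  if (is.name(ex)) return(invisible(TRUE))
  if (is.call(ex)) {
    op <- as.character(ex[[1]])
    if (!op %in% c("&", "|", "!", "("))
      stop("rule may only use AND/OR/NOT and flag names", call. = FALSE)
    for (i in 2:length(ex)) check_bool_ast(ex[[i]])
    return(invisible(TRUE))
  }
  stop("rule may only use AND/OR/NOT and flag names", call. = FALSE)
}

#' Full offline spike detection on one channel
#'
#' Band-pass filter, threshold-crossing candidates, amplitude / width
#' measurement, optional template matching and artifact veto, then
#' Boolean combination of the per-criterion flags.
#'
#' @param rec raw single-channel [recording()].
#' @param criteria a [spike_criteria()].
#' @param artifact an [artifact_criteria()] (default: no veto).
#' @param rule Boolean rule over the flags `amplitude`, `width`,
#'   `template`, `artifact`. The default accepts amplitude+width events or
#'   strong template matches, minus artifacts (template clause dropped
#'   automatically when no template is configured).
#' @return data.frame of accepted events
#'   `(time, amplitude, width, template_score, amplitude/width/template/
#'   artifact flags)`, sorted by time.
#' @export
detect_spikes <- function(rec, criteria = spike_criteria(),
                          artifact = artifact_criteria(),
                          rule = NULL) {
  filt <- bandpass_filter(rec, criteria$band, criteria$filter_order)
  cand <- detect_threshold_crossings(filt, criteria$threshold,
                                     criteria$polarity, criteria$refractory)
  if (is.null(rule))
    rule <- if (is.null(criteria$template))
      "(amplitude AND width) AND NOT artifact"
    else "((amplitude AND width) OR template) AND NOT artifact"
  if (nrow(cand) == 0) {
    out <- data.frame(time = numeric(0), amplitude = numeric(0),
                      width = numeric(0), template_score = numeric(0),
                      amplitude_ok = logical(0), width_ok = logical(0),
                      template = logical(0), artifact = logical(0))
    return(out)
  }
  xf <- rec_channel(filt, 1L)
  meas <- lapply(cand$time, function(t)
    measure_spike_vec(xf, filt$sampling_rate, filt$t0, t,
                      criteria$measure_window / 2, criteria$polarity))
  out <- data.frame(time = cand$time,
                    amplitude_value = vapply(meas, `[[`, 0, "amplitude"),
                    width_value = vapply(meas, `[[`, 0, "width"),
                    template_score = if (is.null(criteria$template))
                      NA_real_
                    else vapply(cand$time, function(t)
                      template_match_vec(xf, filt$sampling_rate, filt$t0,
                                         t, criteria$template), 0))
  out$amplitude <- out$amplitude_value > 0   # supra-threshold by construction
  out$width <- out$width_value >= criteria$width_bounds[1] &
               out$width_value <= criteria$width_bounds[2]
  out$template <- if (is.null(criteria$template)) FALSE else
    out$template_score >= criteria$template_min_score
  out <- reject_artifacts(rec, out, artifact)
  acc <- combine_criteria(out, rule)
  acc[order(acc$time), , drop = FALSE]
}
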