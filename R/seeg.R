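#' Classify the FC / AH onset pattern of one seizure
#'
#' Applies the differential-onset rule: when clear ictal onsets in the
#' fasciola cinereum (FC) and the amygdala / anterior hippocampus (AH)
#' are separated by 50 ms or more, the seizure spread from the earlier
#' region; separations under 50 ms are simultaneous. Exactly 50 ms counts
#' as differential (the rule is "50 ms or more"). A region without an
#' onset is not involved.
#'
#' @param fc_onset,ah_onset onset times in s, or `NA` for not involved.
#' @param threshold differential-onset threshold, s (default 0.050).
#' @return one of `"neither"`, `"FC_without_AH"`, `"AH_without_FC"`,
#'   `"simultaneous_FC_AH"`, `"spread_FC_to_AH"`, `"spread_AH_to_FC"`.
#' @export
#' @examples
#' classify_onset(0.1, 0)    # AH leads by 100 ms -> spread_AH_to_FC
#' classify_onset(0, 0)      # simultaneous
#' classify_onset(NA, 0.2)   # AH involved without FC
classify_onset <- function(fc_onset, ah_onset, threshold = 0.050) {
  fc_in <- !is.na(fc_onset); ah_in <- !is.na(ah_onset)
  if (!fc_in && !ah_in) return("neither")
  if (fc_in && !ah_in) return("FC_without_AH")
  if (!fc_in && ah_in) return("AH_without_FC")
  dt <- fc_onset - ah_onset
  if (abs(dt) < threshold) return("simultaneous_FC_AH")
  if (dt > 0) "spread_AH_to_FC" else "spread_FC_to_AH"
}

#' Classify every seizure of an onset table
#'
#' Takes a per-seizure, per-channel onset table (e.g. from
#' [generate_seeg_case()], or expert-marked), reduces each seizure to its
#' earliest FC and earliest AH onset, and applies [classify_onset()].
#'
#' @param onsets data.frame `(seizure, channel, region, involved,
#'   onset_time)`; regions `"FC"` and `"AH"` are used.
#' @param threshold s.
#' @return data.frame `(seizure, fc_onset, ah_onset, pattern)`.
#' @export
classify_case <- function(onsets, threshold = 0.050) {
  sz <- sort(unique(onsets$seizure))
  rows <- lapply(sz, function(s) {
    sub <- onsets[onsets$seizure == s, ]
    fc <- sub$onset_time[sub$region == "FC" & !is.na(sub$onset_time)]
    ah <- sub$onset_time[sub$region == "AH" & !is.na(sub$onset_time)]
    fc1 <- if (length(fc)) min(fc) else NA_real_
    ah1 <- if (length(ah)) min(ah) else NA_real_
    data.frame(seizure = s, fc_onset = fc1, ah_onset = ah1,
               pattern = classify_onset(fc1, ah1, threshold))
  })
  do.call(rbind, rows)
}

#' Involvement tally for one region
#'
#' Counts seizures with a recorded onset in the region; the fraction is
#' kept exact and rounded to the nearest integer percent only at report
#' time.
#'
#' @param onsets onset table as in [classify_case()], or a logical vector
#'   of per-seizure involvement.
#' @param region region label (when `onsets` is a table).
#' @return list `(n_involved, n_total, fraction, fraction_rounded)` with
#'   `fraction` in percent.
#' @export
#' @examples
#' involvement_fraction(c(rep(TRUE, 15), rep(FALSE, 3)))  # 15 of 18 -> 83%
involvement_fraction <- function(onsets, region = "FC") {
  if (is.data.frame(onsets)) {
    sz <- unique(onsets$seizure)
    inv <- vapply(sz, function(s)
      any(!is.na(onsets$onset_time[onsets$seizure == s &
                                   onsets$region == region])), TRUE)
  } else inv <- as.logical(onsets)
  n <- length(inv)
  if (n < 1) stop("no seizures to tally")
  k <- sum(inv)
  list(n_involved = k, n_total = n, fraction = 100 * k / n,
       fraction_rounded = round(100 * k / n))
}

#' Flag windows containing high-frequency oscillations
#'
#' Band-passes the channel to the HFO band (default 80-250 Hz, requiring
#' the clinical 1,000 Hz sampling rate or better), computes the envelope
#' as the magnitude of the analytic signal, and flags non-overlapping
#' windows whose mean envelope exceeds `threshold` robust SDs above the
#' median envelope.
#'
#' @param rec single-channel [recording()].
#' @param band c(low, high) Hz.
#' @param window window length, s.
#' @param threshold robust-SD multiples.
#' @return data.frame `(start, end, mean_envelope, flagged)`, one row per
#'   window.
#' @export
hfo_band_marker <- function(rec, band = c(80, 250), window = 0.5,
                            threshold = 5) {
  fs <- rec$sampling_rate
  if (fs <= 2 * band[2])
    stop("sampling rate must exceed twice the band's upper edge")
  bf <- butter_coefs(band, 4, fs)
  xb <- signal::filtfilt(bf, rec_channel(rec, 1L))
  env <- Mod(analytic_signal(xb))
  wlen <- max(1L, round(window * fs))
  nwin <- floor(length(env) / wlen)
  if (nwin == 0) return(data.frame(start = numeric(0), end = numeric(0),
                                   mean_envelope = numeric(0),
                                   flagged = logical(0)))
  me <- vapply(seq_len(nwin), function(k)
    mean(env[((k - 1) * wlen + 1):(k * wlen)]), 0)
  thr <- stats::median(env) + threshold * robust_sd(env)
  data.frame(start = rec$t0 + (seq_len(nwin) - 1) * window,
             end = rec$t0 + seq_len(nwin) * window,
             mean_envelope = me,
             flagged = me > thr)
}

# FFT analytic signal (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Percent reduction in seizure frequency
#'
#' `100 * (1 - rate_after / rate_before)`; rates may be in any common
#' unit (e.g. events per month).
#'
#' @param rate_before,rate_after events per unit time; `rate_before > 0`.
#' @return percent reduction (exact; round at report time).
#' @export
#' @examples
#' seizure_frequency_reduction(2, 1 / 3)  # 2/month down to 1 per 3 months
seizure_frequency_reduction <- function(rate_before, rate_after) {
  if (rate_before <= 0) stop("rate_before must be > 0")
  100 * (1 - rate_after / rate_before)
}
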