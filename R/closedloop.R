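#' Trigger policy for the online detector
#'
#' A trigger fires when at least `n_spikes_to_trigger` causally detected
#' spikes fall within a sliding `trigger_window`; after a trigger the
#' detector is locked out for `lockout` seconds. This N-spikes-in-window
#' rule is the minimal trigger consistent with spike-cluster seizures and
#' supports latency analysis; its parameters are experimenter inputs.
#'
#' @param n_spikes_to_trigger count (>= 1).
#' @param trigger_window s.
#' @param lockout refractory after a trigger, s.
#' @param mode `"on_during_seizure"` (light continuously on from trigger
#'   to seizure end) or `"pulse_train"` (fixed pulse schedule from the
#'   trigger, as used for activity labeling).
#' @return list of class `"trigger_policy"`.
#' @export
trigger_policy <- function(n_spikes_to_trigger = 3, trigger_window = 2,
                           lockout = 30,
                           mode = c("on_during_seizure", "pulse_train")) {
  mode <- match.arg(mode)
  if (n_spikes_to_trigger < 1) stop("n_spikes_to_trigger must be >= 1")
  if (lockout < 0) stop("lockout must be >= 0")
  structure(list(n_spikes_to_trigger = n_spikes_to_trigger,
                 trigger_window = trigger_window, lockout = lockout,
                 mode = mode),
            class = "trigger_policy")
}

#' Stimulation pulse schedule
#'
#' Defaults encode 2 s pulses every 6 s (33% duty cycle) for a total of
#' 10 minutes, the activity-labeling protocol; `power_label` is metadata
#' only (mW at the source).
#'
#' @param pulse_on s the light is on per pulse.
#' @param pulse_period s between pulse starts (>= `pulse_on`).
#' @param total total scheduled span, s.
#' @param power_label mW, annotation only.
#' @return list of class `"stim_schedule"` with a `duty_cycle` field.
#' @export
stim_schedule <- function(pulse_on = 2, pulse_period = 6, total = 600,
                          power_label = NULL) {
  if (pulse_on <= 0 || pulse_on > pulse_period)
    stop("need 0 < pulse_on <= pulse_period")
  structure(list(pulse_on = pulse_on, pulse_period = pulse_period,
                 total = total, power_label = power_label,
                 duty_cycle = pulse_on / pulse_period),
            class = "stim_schedule")
}

#' Expand a trigger into its light-pulse intervals
#'
#' Pulses start at `trigger + k * pulse_period` for `k = 0, 1, ...` while
#' the start lies within `total` seconds of the trigger; each pulse lasts
#' `pulse_on` seconds.
#'
#' @param trigger_time s.
#' @param schedule a [stim_schedule()].
#' @return 2-column matrix of `[on, off)` intervals, s.
#' @export
#' @examples
#' nrow(schedule_pulses(0, stim_schedule()))  # 100 pulses over 10 min
schedule_pulses <- function(trigger_time, schedule) {
  starts <- seq(0, schedule$total - 1e-9, by = schedule$pulse_period)
  cbind(on = trigger_time + starts,
        off = trigger_time + starts + schedule$pulse_on)
}

# --- causal streaming detector -------------------------------------------

#' Create streaming detector state
#'
#' The online detector mirrors the offline criteria causally: a causal
#' Butterworth band-pass (same coefficients as the offline zero-phase
#' filter, applied forward only), a running robust-SD threshold estimated
#' from a trailing baseline buffer (refreshed every `update_s` seconds,
#' frozen during the initial `baseline_s` warm-up during which detection
#' is disabled), excursion-extremum spike detection with refractory, and
#' the N-spikes-in-window trigger rule. Every decision at time t uses only
#' samples at or before t, so output is invariant to how the signal is
#' chunked.
#'
#' @param sampling_rate Hz.
#' @param criteria a [spike_criteria()] (band, order, threshold, polarity,
#'   refractory are used).
#' @param policy a [trigger_policy()].
#' @param baseline_s trailing baseline buffer length, s.
#' @param update_s threshold refresh interval, s.
#' @return opaque state list; feed with [stream_feed()].
#' @export
stream_state <- function(sampling_rate, criteria = spike_criteria(),
                         policy = trigger_policy(),
                         baseline_s = 15, update_s = 5) {
  bf <- butter_coefs(criteria$band, criteria$filter_order, sampling_rate)
  list(fs = sampling_rate, criteria = criteria, policy = policy,
       b = bf$b, a = bf$a,
       xprev = rep(0, length(bf$b) - 1), yprev = rep(0, length(bf$a) - 1),
       n = 0L,
       baseline_n = round(baseline_s * sampling_rate),
       update_n = round(update_s * sampling_rate),
       basebuf = numeric(0), thr = Inf,
       in_exc = FALSE, cur_max = -Inf, cur_idx = NA_integer_,
       last_spike = -Inf, recent = numeric(0),
       last_trigger = -Inf,
       spikes = numeric(0), triggers = numeric(0))
}

# causal IIR filtering of one chunk with carried state (bit-exact across
# arbitrary chunkings; verified against whole-signal filtering)
causal_filter_chunk <- function(state, x) {
  xx <- c(state$xprev, x)
  v <- as.numeric(stats::filter(xx, state$b, method = "convolution",
                                sides = 1))[(length(state$xprev) + 1):length(xx)]
  y <- as.numeric(stats::filter(v, -state$a[-1], method = "recursive",
                                init = rev(state$yprev)))
  state$xprev <- tail(xx, length(state$b) - 1)
  state$yprev <- tail(c(state$yprev, y), length(state$a) - 1)
  list(state = state, y = y)
}

#' Feed samples to the streaming detector
#'
#' @param state from [stream_state()] (or a previous `stream_feed` call).
#' @param x numeric chunk of raw samples (any length >= 1).
#' @return updated state; fields `spikes` and `triggers` accumulate times
#'   in seconds.
#' @export
stream_feed <- function(state, x) {
  cf <- causal_filter_chunk(state, x)
  state <- cf$state
  y <- cf$y
  s <- switch(state$criteria$polarity,
              negative = -y, positive = y, both = abs(y))
  len <- length(s)
  g0 <- state$n                     # global index of sample before chunk
  # segment the chunk at threshold-update boundaries (absolute indices)
  bounds <- seq_len(len)[(g0 + seq_len(len)) %% state$update_n == 0L]
  seg_starts <- c(1L, bounds + 1L)
  seg_ends <- c(bounds, len)
  keep <- seg_starts <= seg_ends
  seg_starts <- seg_starts[keep]; seg_ends <- seg_ends[keep]
  for (k in seq_along(seg_starts)) {
    i0 <- seg_starts[k]; i1 <- seg_ends[k]
    state <- process_segment(state, s[i0:i1], g0 + i0)
    # refresh threshold at the boundary closing this segment
    if (i1 <= len && (g0 + i1) %% state$update_n == 0L &&
        g0 + i1 >= state$baseline_n) {
      sdr <- robust_sd(state$basebuf)
      state$thr <- if (is.finite(sdr) && sdr > 0)
        state$criteria$threshold * sdr else Inf
    }
  }
  state$n <- state$n + len
  state
}

# excursion detection over one fixed-threshold segment
process_segment <- function(state, s, g_first) {
  above <- s > state$thr
  state$basebuf <- tail(c(state$basebuf, s), state$baseline_n)
  if (!any(above) && !state$in_exc) return(state)
  r <- rle(above)
  pos <- 1L
  for (j in seq_along(r$lengths)) {
    n_j <- r$lengths[j]
    idx <- pos:(pos + n_j - 1L)
    if (r$values[j]) {
      m <- which.max(s[idx])
      if (!state$in_exc || s[idx][m] > state$cur_max) {
        if (!state$in_exc) { state$in_exc <- TRUE; state$cur_max <- -Inf }
        if (s[idx][m] > state$cur_max) {
          state$cur_max <- s[idx][m]
          state$cur_idx <- g_first + idx[m] - 1L
        }
      }
    } else if (state$in_exc) {
      state <- emit_spike(state)
    }
    pos <- pos + n_j
  }
  state
}

emit_spike <- function(state) {
  t <- (state$cur_idx - 1L) / state$fs
  state$in_exc <- FALSE; state$cur_max <- -Inf; state$cur_idx <- NA_integer_
  if (t - state$last_spike < state$criteria$refractory) return(state)
  state$last_spike <- t
  state$spikes <- c(state$spikes, t)
  pol <- state$policy
  state$recent <- c(state$recent[state$recent > t - pol$trigger_window], t)
  if (length(state$recent) >= pol$n_spikes_to_trigger &&
      t - state$last_trigger >= pol$lockout) {
    state$last_trigger <- t
    state$triggers <- c(state$triggers, t)
  }
  state
}

#' Run the causal detector over a whole recording
#'
#' Convenience wrapper: creates state, feeds the signal in chunks and
#' returns the trigger log. Results are identical for any chunking,
#' including sample-by-sample replay.
#'
#' @param rec single-channel [recording()].
#' @param criteria a [spike_criteria()].
#' @param policy a [trigger_policy()].
#' @param chunk chunk size in samples (default 4096).
#' @param baseline_s,update_s see [stream_state()].
#' @return list of class `"trigger_log"`: `trigger_times`, `spike_times`,
#'   `threshold` (final), `duration` (s).
#' @export
stream_detect <- function(rec, criteria = spike_criteria(),
                          policy = trigger_policy(), chunk = 4096,
                          baseline_s = 15, update_s = 5) {
  x <- rec_channel(rec, 1L)
  st <- stream_state(rec$sampling_rate, criteria, policy,
                     baseline_s, update_s)
  i <- 1L; n <- length(x)
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    st <- stream_feed(st, x[i:j])
    i <- j + 1L
  }
  structure(list(trigger_times = st$triggers, spike_times = st$spikes,
                 threshold = st$thr, duration = rec_duration(rec)),
            class = "trigger_log")
}

#' Score a trigger log against ground truth
#'
#' A trigger matches the unique truth seizure whose `[onset, offset)`
#' interval contains it; triggers outside every seizure are false.
#' Sensitivity is matched seizures over truth seizures; latency is the
#' first matching trigger minus the seizure onset.
#'
#' @param log a `trigger_log` (or numeric trigger times).
#' @param truth ground truth from [generate_lfp()].
#' @param duration recording length, s (taken from the log if absent).
#' @return list `(sensitivity, n_true, n_matched, false_triggers,
#'   false_per_hour, latency_median, latency_mean)`.
#' @export
evaluate_detection <- function(log, truth, duration = NULL) {
  tt <- if (is.list(log)) log$trigger_times else log
  duration <- duration %||% (if (is.list(log)) log$duration else
    stop("duration required"))
  iv <- truth$seizure_intervals
  n_true <- nrow(iv)
  match_of <- if (n_true > 0 && length(tt) > 0)
    vapply(tt, function(t) {
      k <- which(t >= iv[, 1] & t < iv[, 2])
      if (length(k) == 1L) k else NA_integer_
    }, 1L)
  else rep(NA_integer_, length(tt))
  matched <- unique(match_of[!is.na(match_of)])
  lat <- vapply(matched, function(k)
    min(tt[!is.na(match_of) & match_of == k]) - iv[k, 1], 0)
  n_false <- sum(is.na(match_of))
  list(sensitivity = if (n_true == 0) NA_real_ else length(matched) / n_true,
       n_true = n_true, n_matched = length(matched),
       false_triggers = n_false,
       false_per_hour = n_false / (duration / 3600),
       latency_median = if (length(lat)) stats::median(lat) else NA_real_,
       latency_mean = if (length(lat)) mean(lat) else NA_real_)
}

#' Simulate one complete closed-loop session
#'
#' Generates a synthetic LFP session, streams the causal detector over
#' it, applies the light intervention (post-trigger truncation) to
#' triggered seizures when `light_on`, re-segments the modified signal
#' offline (zero-phase detection + cluster segmentation, which is
#' authoritative for durations), and emits one row per triggered seizure
#' with its duration from trigger.
#'
#' @param config a [gen_config()]; its `truncation_factor` is applied in
#'   light-on sessions.
#' @param criteria a [spike_criteria()] shared by the online and offline
#'   detectors.
#' @param policy a [trigger_policy()].
#' @param schedule a [stim_schedule()] (used in `pulse_train` mode).
#' @param light_on logical; light-off sessions run the identical pipeline
#'   with stimulation disabled.
#' @return list with `durations` (data.frame `condition, trigger_time,
#'   duration_from_trigger`), `log`, `truth`, `seizures` (offline
#'   segmentation), `evaluation`.
#' @export
run_closed_loop_session <- function(config, criteria = spike_criteria(),
                                    policy = trigger_policy(),
                                    schedule = stim_schedule(),
                                    light_on = TRUE) {
  session <- generate_lfp(config)
  log <- stream_detect(session$recording, criteria, policy)
  iv <- session$truth$seizure_intervals
  # first trigger inside each truth seizure (the analysis trigger)
  in_seiz <- numeric(0)
  if (nrow(iv) > 0 && length(log$trigger_times) > 0) {
    hit <- vapply(log$trigger_times, function(t) {
      k <- which(t >= iv[, 1] & t < iv[, 2])
      if (length(k) == 1L) k else NA_integer_
    }, 1L)
    ok <- !is.na(hit) & !duplicated(hit)
    in_seiz <- log$trigger_times[ok]
  }
  if (light_on && length(in_seiz) > 0) {
    session <- apply_intervention(session, in_seiz,
                                  config$truncation_factor, config)
    if (policy$mode == "pulse_train") {
      session$truth$light_intervals <-
        do.call(rbind, lapply(in_seiz, schedule_pulses, schedule = schedule))
    }
  }
  spikes <- detect_spikes(session$recording, criteria)
  seiz <- cluster_spikes(spikes$time)
  rows <- lapply(in_seiz, function(tt) {
    k <- which(tt >= seiz$onset & tt <= seiz$end)
    if (length(k) != 1L) return(NULL)
    data.frame(condition = if (light_on) "light_on" else "light_off",
               trigger_time = tt,
               duration_from_trigger = seiz$end[k] - tt)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(rows))
    rows <- data.frame(condition = character(0), trigger_time = numeric(0),
                       duration_from_trigger = numeric(0))
  list(durations = rows, log = log, truth = session$truth,
       seizures = seiz,
       evaluation = evaluate_detection(log, session$truth))
}
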