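# Independent reference implementations used as oracles. These deliberately
# take a different algorithmic route from the package code.

# O(n^2)-style scanning segmenter: walk the train looking for a dense run,
# then extend its end through sub-end_gap gaps.
bf_segment <- function(ts, max_isi = 1, min_spikes = 3, end_gap = 2) {
  n <- length(ts)
  out <- NULL
  i <- 1L
  while (i <= n) {
    j <- i
    while (j + 1L <= n && ts[j + 1L] - ts[j] < max_isi) j <- j + 1L
    if (j - i + 1L >= min_spikes) {
      k <- j
      while (k + 1L <= n && ts[k + 1L] - ts[k] < end_gap) k <- k + 1L
      out <- rbind(out, c(ts[i], ts[k], k - i + 1L))
      i <- k + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out))
    out <- matrix(numeric(0), ncol = 3)
  colnames(out) <- c("onset", "end", "n_spikes")
  out
}

# truth-table evaluator: substitute each event's flags into the rule string
# and eval the resulting literal expression
bf_combine <- function(events, rule) {
  s <- gsub("\\bAND\\b", "&", rule, ignore.case = TRUE)
  s <- gsub("\\bOR\\b", "|", s, ignore.case = TRUE)
  s <- gsub("\\bNOT\\b", "!", s, ignore.case = TRUE)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    expr <- s
    for (v in names(events)) {
      if (is.logical(events[[v]]))
        expr <- gsub(paste0("\\b", v, "\\b"), as.character(events[[v]][i]),
                     expr)
    }
    isTRUE(eval(parse(text = expr)))
  }, TRUE)
  events[keep, , drop = FALSE]
}

# per-event, per-bin double-loop peri-event average
bf_peri_event <- function(dff, frame_times, event_times, pre, post, bin) {
  centers <- seq(-pre, post, by = bin)
  t0 <- frame_times[1]; t1 <- frame_times[length(frame_times)]
  acc <- matrix(0, nrow(dff), length(centers))
  cnt <- integer(length(centers))
  for (ev in event_times[event_times >= t0 & event_times <= t1]) {
    for (b in seq_along(centers)) {
      t <- ev + centers[b]
      if (t < t0 || t > t1) next
      f <- which.min(abs(frame_times - t))
      acc[, b] <- acc[, b] + dff[, f]
      cnt[b] <- cnt[b] + 1L
    }
  }
  sweep(acc, 2, pmax(cnt, 1L), "/")
}

# small noise-free session with one seizure built by hand (no RNG)
make_toy_session <- function(fs = 500, duration = 40,
                             seizure = c(10, 20), isi = 0.3,
                             interictal = c(3, 30), amplitude = 8) {
  wf <- spike_waveform(0.04, amplitude, fs)
  x <- numeric(duration * fs)
  sp <- seq(seizure[1], seizure[2] - 1e-9, by = isi)
  x <- ictaloop:::insert_waveforms(x, sp, wf, fs)
  x <- ictaloop:::insert_waveforms(x, interictal, wf, fs)
  truth <- list(interictal_spike_times = interictal,
                seizure_intervals = matrix(seizure, ncol = 2,
                                           dimnames = list(NULL, c("onset", "offset"))),
                per_seizure_spike_times = list(sp),
                light_intervals = matrix(numeric(0), ncol = 2),
                applied_truncation_factor = NA_real_,
                no_seizures_possible = FALSE)
  list(recording = recording(x, fs, "lfp"), truth = truth)
}

# match detected event times against truth times with a tolerance
match_events <- function(detected, truth, tol = 0.025) {
  hits <- vapply(truth, function(t) any(abs(detected - t) <= tol), TRUE)
  false_pos <- vapply(detected, function(t) all(abs(truth - t) > tol), TRUE)
  list(sensitivity = mean(hits), n_false = sum(false_pos))
}
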