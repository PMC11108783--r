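#' Configuration for synthetic session generation
#'
#' Collects every free parameter of the synthetic LFP / calcium / sEEG
#' generators in one validated list. Defaults describe a 10-minute mouse
#' hippocampal LFP session sampled at 500 Hz with isolated interictal
#' spikes and spike-cluster seizures, plus a calcium indicator imaged at
#' 15.49 frames per second.
#'
#' @param sampling_rate LFP sampling rate, Hz.
#' @param duration session length, s.
#' @param gaussian_sigma white-noise SD, signal units.
#' @param pink_exponent exponent of an optional 1/f^a noise component
#'   (0 disables it); `pink_scale` sets its SD relative to `gaussian_sigma`.
#' @param pink_scale see `pink_exponent`.
#' @param spike_width total width of the biphasic spike transient, s.
#' @param spike_amplitude peak (negative-lobe) amplitude, signal units.
#' @param interictal_rate Poisson rate of isolated interictal spikes, /s.
#' @param seizure_rate Poisson rate of seizure onsets, /s.
#' @param seizure_meanlog,seizure_sdlog lognormal seizure-duration
#'   parameters (`seizure_meanlog` is the log of the median duration in s).
#' @param isi_mean,isi_sd within-seizure interspike-interval mean and SD, s;
#'   the mean must stay below 1 s so generated seizures satisfy the
#'   cluster-inclusion rule.
#' @param isi_min hard floor on within-seizure ISIs, s.
#' @param truncation_factor multiplicative shortening of the post-trigger
#'   seizure duration applied by [apply_intervention()]; in (0, 1].
#' @param frame_rate calcium imaging frame rate, Hz.
#' @param rise_tau,decay_tau calcium indicator kernel time constants, s
#'   (`decay_tau > rise_tau`).
#' @param ca_spike_amplitude latent calcium impulse per interictal spike.
#' @param ca_seizure_gain sustained latent elevation during a seizure.
#' @param ca_noise_sigma additive noise SD on fluorescence traces.
#' @param seed integer seed; every sub-generator derives an independent
#'   stream from it, so e.g. adding calcium cells never changes the LFP.
#'
#' @return A list of class `"gen_config"`.
#' @export
gen_config <- function(sampling_rate = 500, duration = 600,
                       gaussian_sigma = 1, pink_exponent = 0, pink_scale = 0.5,
                       spike_width = 0.04, spike_amplitude = 8,
                       interictal_rate = 0.1, seizure_rate = 0.01,
                       seizure_meanlog = log(12), seizure_sdlog = 0.4,
                       isi_mean = 0.3, isi_sd = 0.1, isi_min = 0.05,
                       truncation_factor = 1,
                       frame_rate = 15.49, rise_tau = 0.05, decay_tau = 0.5,
                       ca_spike_amplitude = 0.3, ca_seizure_gain = 1,
                       ca_noise_sigma = 0.05,
                       seed = 1L) {
  cfg <- list(sampling_rate = sampling_rate, duration = duration,
              gaussian_sigma = gaussian_sigma, pink_exponent = pink_exponent,
              pink_scale = pink_scale,
              spike_width = spike_width, spike_amplitude = spike_amplitude,
              interictal_rate = interictal_rate, seizure_rate = seizure_rate,
              seizure_meanlog = seizure_meanlog, seizure_sdlog = seizure_sdlog,
              isi_mean = isi_mean, isi_sd = isi_sd, isi_min = isi_min,
              truncation_factor = truncation_factor,
              frame_rate = frame_rate, rise_tau = rise_tau,
              decay_tau = decay_tau,
              ca_spike_amplitude = ca_spike_amplitude,
              ca_seizure_gain = ca_seizure_gain,
              ca_noise_sigma = ca_noise_sigma,
              seed = as.integer(seed))
  validate_gen_config(cfg)
  structure(cfg, class = "gen_config")
}

validate_gen_config <- function(cfg) {
  with(cfg, {
    if (sampling_rate <= 0) stop("sampling_rate must be > 0")
    if (duration <= 0) stop("duration must be > 0")
    if (interictal_rate < 0 || seizure_rate < 0) stop("rates must be >= 0")
    if (truncation_factor <= 0 || truncation_factor > 1)
      stop("truncation_factor must be in (0, 1]")
    if (isi_mean >= 1)
      stop("within-seizure ISI mean must be < 1 s (cluster-inclusion rule)")
    if (decay_tau <= rise_tau) stop("decay_tau must exceed rise_tau")
    if (frame_rate <= 0) stop("frame_rate must be > 0")
  })
  invisible(cfg)
}

#' Canonical biphasic epileptiform spike waveform
#'
#' A sharp negative half-sine deflection followed by a slower, smaller
#' positive rebound. Detection criteria (amplitude, width at half maximum,
#' template score) all have well-defined values on this shape.
#'
#' @param width total waveform duration, s (negative lobe takes the first
#'   half, rebound the second).
#' @param amplitude magnitude of the negative lobe, signal units.
#' @param sampling_rate Hz.
#' @return numeric vector of samples (length `round(width * sampling_rate)`).
#' @export
spike_waveform <- function(width = 0.04, amplitude = 1, sampling_rate = 500) {
  n <- max(3L, round(width * sampling_rate))
  n1 <- max(2L, round(n / 2))
  n2 <- n - n1
  lobe1 <- -amplitude * sin(pi * seq_len(n1) / (n1 + 1))
  lobe2 <- if (n2 > 0) 0.4 * amplitude * sin(pi * seq_len(n2) / (n2 + 1))
           else numeric(0)
  c(lobe1, lobe2)
}

# Add a waveform into `x` centred so its extremum lands at sample index of
# time t. Returns modified signal; vectorized over event times.
insert_waveforms <- function(x, times, wf, sampling_rate, scale = 1) {
  if (length(times) == 0) return(x)
  if (length(scale) == 1) scale <- rep(scale, length(times))
  peak_off <- which.min(wf) - 1L            # extremum sample within waveform
  n <- length(x); m <- length(wf)
  for (k in seq_along(times)) {
    i0 <- round(times[k] * sampling_rate) + 1L - peak_off
    i1 <- i0 + m - 1L
    if (i0 >= 1L && i1 <= n) {
      x[i0:i1] <- x[i0:i1] + scale[k] * wf
    } else {
      idx <- i0:i1
      keep <- idx >= 1L & idx <= n
      if (any(keep)) x[idx[keep]] <- x[idx[keep]] + scale[k] * wf[keep]
    }
  }
  x
}

# 1/f^a noise via spectral shaping of white noise (deterministic given RNG state)
pink_noise <- function(n, exponent) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                 # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)                   # symmetric frequency index
  sp <- sp / f^(exponent / 2)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  as.numeric(scale(x))                      # unit SD
}

#' Generate a synthetic LFP session with ground truth
#'
#' Background noise (Gaussian white, plus an optional 1/f component) with
#' biphasic spike waveforms added at isolated interictal times (homogeneous
#' Poisson) and in clusters during seizure intervals. Seizure onsets follow
#' a Poisson process; durations are lognormal; within-seizure interspike
#' intervals are truncated-normal with mean below 1 s, so every generated
#' seizure satisfies the cluster-inclusion rule by construction.
#' Overlapping seizure draws are thinned (first onset wins) and interictal
#' spikes falling within 3 s of a seizure are dropped, keeping the truth
#' unambiguous. Deterministic given `config$seed`.
#'
#' @param config a [gen_config()].
#' @return list with elements `recording` (a [recording()]) and `truth`, a
#'   list with `interictal_spike_times`, `seizure_intervals` (2-column
#'   matrix of half-open `[onset, offset)` in s), `per_seizure_spike_times`
#'   (list of numeric vectors), `light_intervals` (2-column matrix, empty
#'   until [apply_intervention()]), `applied_truncation_factor`, and
#'   `no_seizures_possible` flag set when the session is too short to hold
#'   one seizure.
#' @export
#' @examples
#' s <- generate_lfp(gen_config(duration = 60, seed = 42))
#' nrow(s$truth$seizure_intervals)
generate_lfp <- function(config) {
  validate_gen_config(config)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  wf <- spike_waveform(config$spike_width, config$spike_amplitude, fs)

  noise <- withr::with_seed(derive_seed(config$seed, 1), {
    x <- stats::rnorm(n, sd = config$gaussian_sigma)
    if (config$pink_exponent > 0)
      x <- x + config$pink_scale * config$gaussian_sigma *
        pink_noise(n, config$pink_exponent)
    x
  })

  ev <- withr::with_seed(derive_seed(config$seed, 2),
                         draw_events(config))

  x <- noise
  x <- insert_waveforms(x, ev$interictal, wf, fs)
  for (sp in ev$per_seizure) x <- insert_waveforms(x, sp, wf, fs)

  truth <- list(
    interictal_spike_times = ev$interictal,
    seizure_intervals = ev$intervals,
    per_seizure_spike_times = ev$per_seizure,
    light_intervals = matrix(numeric(0), ncol = 2,
                             dimnames = list(NULL, c("on", "off"))),
    applied_truncation_factor = NA_real_,
    no_seizures_possible = isTRUE(ev$no_seizures_possible))

  list(recording = recording(x, fs, "lfp"), truth = truth)
}

# Draw interictal spike times, seizure intervals and within-seizure spike
# trains for one session (uses the current RNG stream).
draw_events <- function(config) {
  dur <- config$duration
  # seizures: Poisson onsets, lognormal durations, overlap-thinned
  intervals <- matrix(numeric(0), ncol = 2)
  per_seizure <- list()
  no_seiz_flag <- FALSE
  min_seiz <- 3 * config$isi_mean          # room for a minimal cluster
  if (config$seizure_rate > 0) {
    if (dur <= min_seiz + 1) no_seiz_flag <- TRUE
    n_on <- stats::rpois(1, config$seizure_rate * dur)
    if (n_on > 0 && !no_seiz_flag) {
      onsets <- sort(stats::runif(n_on, 1, dur - 1))
      durs <- stats::rlnorm(n_on, config$seizure_meanlog, config$seizure_sdlog)
      durs <- pmax(durs, min_seiz)
      keep_on <- numeric(0); keep_off <- numeric(0); last_off <- -Inf
      for (k in seq_len(n_on)) {
        if (onsets[k] >= last_off + 3 && onsets[k] + durs[k] < dur) {
          keep_on <- c(keep_on, onsets[k])
          keep_off <- c(keep_off, onsets[k] + durs[k])
          last_off <- onsets[k] + durs[k]
        }
      }
      intervals <- cbind(onset = keep_on, offset = keep_off)
      per_seizure <- lapply(seq_along(keep_on), function(k) {
        t <- keep_on[k]; out <- t
        repeat {
          isi <- max(config$isi_min,
                     stats::rnorm(1, config$isi_mean, config$isi_sd))
          t <- t + isi
          if (t >= keep_off[k]) break
          out <- c(out, t)
        }
        out
      })
      # a seizure interval must actually contain a cluster
      ok <- vapply(per_seizure, length, 1L) >= 3L
      intervals <- intervals[ok, , drop = FALSE]
      per_seizure <- per_seizure[ok]
    }
  }
  # interictal spikes: homogeneous Poisson, kept clear of seizures
  interictal <- numeric(0)
  if (config$interictal_rate > 0) {
    n_ii <- stats::rpois(1, config$interictal_rate * dur)
    interictal <- sort(stats::runif(n_ii, 0, dur))
    if (nrow(intervals) > 0) {
      near <- vapply(interictal, function(t)
        any(t >= intervals[, 1] - 3 & t < intervals[, 2] + 3), TRUE)
      interictal <- interictal[!near]
    }
  }
  list(interictal = interictal, intervals = intervals,
       per_seizure = per_seizure, no_seizures_possible = no_seiz_flag)
}

#' Apply a closed-loop light intervention to a synthetic session
#'
#' For each trigger time falling inside a ground-truth seizure, the
#' post-trigger seizure duration is multiplied by `truncation_factor`:
#' the new offset is `trigger + factor * (offset - trigger)`. Truth spikes
#' beyond the new offset are deleted and their waveforms subtracted from
#' the signal, and a light interval `[trigger, new offset)` is recorded.
#' Triggers outside every seizure are ignored with a warning. A factor of
#' 1 leaves the session untouched; factors above 1 (lengthening) are not
#' modeled and are rejected.
#'
#' @param session list with `recording` and `truth` as returned by
#'   [generate_lfp()].
#' @param trigger_times numeric vector, s.
#' @param truncation_factor in (0, 1]; defaults to the generating config's.
#' @param config the [gen_config()] used to generate the session (supplies
#'   the waveform to subtract).
#' @return A session list of the same shape with modified `recording` and
#'   `truth` (including `light_intervals` and `applied_truncation_factor`).
#' @export
apply_intervention <- function(session, trigger_times, truncation_factor,
                               config) {
  if (truncation_factor > 1)
    stop("truncation_factor > 1 (seizure lengthening) is not modeled")
  if (truncation_factor <= 0) stop("truncation_factor must be in (0, 1]")
  truth <- session$truth
  rec <- session$recording
  fs <- rec$sampling_rate
  wf <- spike_waveform(config$spike_width, config$spike_amplitude, fs)
  x <- rec$samples[, 1]
  iv <- truth$seizure_intervals
  lights <- matrix(numeric(0), ncol = 2)
  trigger_times <- sort(trigger_times)
  used <- rep(FALSE, nrow(iv))
  for (tt in trigger_times) {
    k <- which(tt >= iv[, 1] & tt < iv[, 2])
    if (length(k) != 1L) {
      warning(sprintf("trigger at %.3f s falls outside every seizure; ignored",
                      tt))
      next
    }
    if (used[k]) next                       # one truncation per seizure
    used[k] <- TRUE
    new_off <- tt + truncation_factor * (iv[k, 2] - tt)
    drop <- truth$per_seizure_spike_times[[k]] >= new_off
    if (any(drop)) {
      x <- insert_waveforms(x, truth$per_seizure_spike_times[[k]][drop],
                            wf, fs, scale = -1)
      truth$per_seizure_spike_times[[k]] <-
        truth$per_seizure_spike_times[[k]][!drop]
    }
    iv[k, 2] <- new_off
    lights <- rbind(lights, c(tt, new_off))
  }
  truth$seizure_intervals <- iv
  colnames(lights) <- c("on", "off")
  truth$light_intervals <- lights
  truth$applied_truncation_factor <- truncation_factor
  list(recording = recording(x, fs, rec$channel_labels, rec$t0),
       truth = truth)
}

# Analytic response of the difference-of-exponentials indicator kernel
# k(u) = exp(-u/decay) - exp(-u/rise) (u >= 0, peak-normalized below).
ca_kernel_peak <- function(rise, decay) {
  tp <- (rise * decay / (decay - rise)) * log(decay / rise)
  exp(-tp / decay) - exp(-tp / rise)
}

ca_impulse <- function(t, rise, decay) {
  out <- numeric(length(t))
  p <- t >= 0
  out[p] <- (exp(-t[p] / decay) - exp(-t[p] / rise)) / ca_kernel_peak(rise, decay)
  out
}

# step response: integral of the peak-normalized kernel from 0 to t
ca_step <- function(t, rise, decay) {
  out <- numeric(length(t))
  p <- t >= 0
  out[p] <- (decay * (1 - exp(-t[p] / decay)) -
             rise * (1 - exp(-t[p] / rise))) / ca_kernel_peak(rise, decay)
  out
}

#' Generate synthetic calcium traces coupled to LFP ground truth
#'
#' Each cell's latent activity receives an impulse at every interictal and
#' within-seizure spike (amplitude `ca_spike_amplitude` times a per-cell
#' gain) and a sustained elevation `ca_seizure_gain` during each seizure
#' interval, shaped by a difference-of-exponentials indicator kernel
#' (`rise_tau`, `decay_tau`) evaluated analytically on the frame grid.
#' Resting fluorescence is 1 unit per cell so dF/F is well defined;
#' Gaussian noise `ca_noise_sigma` is added per frame.
#'
#' @param truth ground-truth list from [generate_lfp()].
#' @param n_cells number of cells (>= 1).
#' @param config a [gen_config()].
#' @return list with `traces` (cells x frames fluorescence matrix),
#'   `frame_times` (s), and `cell_gains`.
#' @export
generate_calcium <- function(truth, n_cells, config) {
  validate_gen_config(config)
  if (n_cells < 1) stop("n_cells must be >= 1")
  ft <- seq(0, config$duration - 1 / config$frame_rate,
            by = 1 / config$frame_rate)
  rise <- config$rise_tau; decay <- config$decay_tau
  spike_times <- sort(c(truth$interictal_spike_times,
                        unlist(truth$per_seizure_spike_times)))
  iv <- truth$seizure_intervals

  base <- numeric(length(ft))
  for (st in spike_times)
    base <- base + config$ca_spike_amplitude * ca_impulse(ft - st, rise, decay)
  seiz <- numeric(length(ft))
  if (nrow(iv) > 0) for (k in seq_len(nrow(iv)))
    seiz <- seiz + config$ca_seizure_gain *
      (ca_step(ft - iv[k, 1], rise, decay) - ca_step(ft - iv[k, 2], rise, decay)) *
      ca_kernel_peak(rise, decay) / (decay - rise)   # unit plateau
  latent <- base + seiz

  traces <- matrix(0, nrow = n_cells, ncol = length(ft))
  gains <- numeric(n_cells)
  for (c_i in seq_len(n_cells)) {
    cell <- withr::with_seed(derive_seed(config$seed, 100 + c_i), {
      g <- stats::runif(1, 0.7, 1.3)
      list(gain = g,
           trace = 1 + g * latent +
             stats::rnorm(length(ft), sd = config$ca_noise_sigma))
    })
    traces[c_i, ] <- cell$trace
    gains[c_i] <- cell$gain
  }
  list(traces = traces, frame_times = ft, cell_gains = gains)
}

#' Render calcium traces as a synthetic movie with ROI masks
#'
#' Each cell becomes a disk of pixels on a frame grid; within a frame every
#' pixel of the disk takes the cell's trace value plus independent pixel
#' noise, so the disk mean equals the trace value in the noise-free case
#' and mask-based extraction is an exact round trip.
#'
#' @param traces cells x frames matrix.
#' @param frame_dim c(rows, cols) of the movie frames.
#' @param radius disk radius in pixels.
#' @param pixel_noise SD of per-pixel additive noise.
#' @param seed integer seed for pixel noise.
#' @return list with `movie` (frames x rows x cols array) and `masks`
#'   (integer rows x cols label matrix, 0 = background, k = cell k).
#' @export
render_calcium_movie <- function(traces, frame_dim = c(32, 32), radius = 2,
                                 pixel_noise = 0, seed = 1L) {
  n_cells <- nrow(traces); n_frames <- ncol(traces)
  rows <- frame_dim[1]; cols <- frame_dim[2]
  # non-overlapping disk centres on a grid
  per_row <- max(1L, floor((cols - 2 * radius) / (2 * radius + 2)))
  centres <- t(vapply(seq_len(n_cells) - 1L, function(k) {
    r <- radius + 2 + (k %/% per_row) * (2 * radius + 2)
    c <- radius + 2 + (k %% per_row) * (2 * radius + 2)
    c(r, c)
  }, numeric(2)))
  if (any(centres[, 1] > rows - radius))
    stop("frame too small for the requested number of cells")
  masks <- matrix(0L, rows, cols)
  pix <- expand.grid(r = seq_len(rows), c = seq_len(cols))
  for (k in seq_len(n_cells)) {
    inside <- (pix$r - centres[k, 1])^2 + (pix$c - centres[k, 2])^2 <= radius^2
    masks[cbind(pix$r[inside], pix$c[inside])] <- k
  }
  movie <- array(0, dim = c(n_frames, rows, cols))
  noise <- if (pixel_noise > 0)
    withr::with_seed(derive_seed(seed, 200),
                     array(stats::rnorm(n_frames * rows * cols, sd = pixel_noise),
                           dim = c(n_frames, rows, cols)))
  else NULL
  for (k in seq_len(n_cells)) {
    sel <- which(masks == k, arr.ind = TRUE)
    for (j in seq_len(nrow(sel)))
      movie[, sel[j, 1], sel[j, 2]] <- traces[k, ]
  }
  if (!is.null(noise)) movie <- movie + noise
  list(movie = movie, masks = masks)
}

#' Generate a synthetic multichannel sEEG case with per-channel onsets
#'
#' Emulates a clinical stereo-EEG recording at 1,000 Hz: for each seizure
#' and each channel, the channel either stays uninvolved or receives an
#' ictal spike-cluster discharge starting at a latency drawn from its
#' region's onset rule. The emitted onset table is the ground truth for
#' onset-pattern classification.
#'
#' @param n_seizures number of seizures.
#' @param channel_plan data.frame with columns `channel`, `region` (e.g.
#'   "FC", "AH", "neocortex").
#' @param onset_rule named list per region: `list(latency_mean, latency_sd,
#'   involvement_prob)`; latencies are s relative to the seizure's base
#'   onset.
#' @param config a [gen_config()] (its `sampling_rate` should be the
#'   clinical 1,000 Hz; `duration` is ignored — the record length follows
#'   from `n_seizures` and `spacing`).
#' @param spacing s between consecutive seizure base onsets (default 30).
#' @param seizure_duration s of each inserted discharge (default 10).
#' @return list with `recording` (multichannel) and `onsets`, a data.frame
#'   `(seizure, channel, region, involved, onset_time)` with `onset_time`
#'   `NA` for uninvolved channels.
#' @export
generate_seeg_case <- function(n_seizures, channel_plan, onset_rule, config,
                               spacing = 30, seizure_duration = 10) {
  if (nrow(channel_plan) < 2) stop("channel plan needs at least 2 channels")
  missing_r <- setdiff(unique(channel_plan$region), names(onset_rule))
  if (length(missing_r) > 0)
    stop("onset_rule missing regions: ", paste(missing_r, collapse = ", "))
  fs <- config$sampling_rate
  total <- n_seizures * spacing + spacing
  n <- round(total * fs)
  wf <- spike_waveform(config$spike_width, config$spike_amplitude, fs)
  base_onsets <- spacing / 2 + (seq_len(n_seizures) - 1) * spacing

  out <- withr::with_seed(derive_seed(config$seed, 3), {
    samp <- matrix(stats::rnorm(n * nrow(channel_plan),
                                sd = config$gaussian_sigma), ncol = nrow(channel_plan))
    rows <- list()
    for (s_i in seq_len(n_seizures)) {
      for (c_i in seq_len(nrow(channel_plan))) {
        reg <- channel_plan$region[c_i]
        rule <- onset_rule[[reg]]
        involved <- stats::runif(1) < rule$involvement_prob
        onset <- NA_real_
        if (involved) {
          lat <- stats::rnorm(1, rule$latency_mean, rule$latency_sd %||% 0)
          onset <- base_onsets[s_i] + max(0, lat)
          sp <- seq(onset, onset + seizure_duration, by = config$isi_mean)
          samp[, c_i] <- insert_waveforms(samp[, c_i], sp, wf, fs)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          seizure = s_i, channel = channel_plan$channel[c_i],
          region = reg, involved = involved, onset_time = onset)
      }
    }
    list(samples = samp, onsets = do.call(rbind, rows))
  })
  list(recording = recording(out$samples, fs, channel_plan$channel),
       onsets = out$onsets)
}
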