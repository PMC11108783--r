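make_sine_rec <- function(freq, fs = 500, duration = 10) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  recording(sin(2 * pi * freq * t), fs)
}

test_that("band-pass removes DC and respects its pass/stop bands", {
  fs <- 500
  const <- recording(rep(3, fs * 5), fs)
  out <- bandpass_filter(const, c(5, 40))
  # away from the filter's edge transients the DC level is fully removed
  expect_lt(max(abs(out$samples[1000:1500, 1])), 1e-6)

  mid <- bandpass_filter(make_sine_rec(15), c(5, 40))
  # drop filter edges before measuring amplitude
  core <- mid$samples[500:4500, 1]
  expect_equal(max(abs(core)), 1, tolerance = 0.05)

  low <- bandpass_filter(make_sine_rec(0.5), c(5, 40))
  expect_lt(max(abs(low$samples[500:4500, 1])), 0.1)
})

test_that("band edges at or beyond Nyquist are rejected", {
  expect_error(bandpass_filter(make_sine_rec(10), c(5, 250)), "Nyquist")
})

test_that("threshold crossings find inserted spikes and respect refractory", {
  fs <- 500
  withr::with_seed(42, {
    x <- rnorm(fs * 60)
    # at 10 robust SDs, pure Gaussian noise yields essentially no candidates
    quiet <- detect_threshold_crossings(recording(x, fs), threshold = 10)
    expect_lte(nrow(quiet), 1)

    wf <- spike_waveform(0.04, 8 * mad(x), fs)
    x1 <- ictaloop:::insert_waveforms(x, 30, wf, fs)
    cand <- detect_threshold_crossings(recording(-x1, fs),
                                       threshold = 5, polarity = "positive")
    # polarity flip: the biphasic trough becomes a peak
    expect_equal(sum(abs(cand$time - 30) <= 0.01), 1)
  })
  # two events 5 ms apart with a 200 ms refractory collapse to one
  wf <- spike_waveform(0.01, 1, fs)
  x <- ictaloop:::insert_waveforms(numeric(fs * 4), c(2, 2.005), wf, fs)
  x <- x + rnorm(length(x), sd = 1e-3)
  cand <- detect_threshold_crossings(recording(x, fs), threshold = 5,
                                     refractory = 0.2)
  expect_equal(nrow(cand), 1)
})

test_that("a zero-variance signal yields no candidates", {
  cand <- detect_threshold_crossings(recording(rep(0, 1000), 500))
  expect_equal(nrow(cand), 0)
})

test_that("FWHM of a triangular pulse is half its base", {
  fs <- 1000
  base <- 0.040
  n <- base * fs
  tri <- c(seq(0, 1, length.out = n / 2), seq(1, 0, length.out = n / 2))
  x <- numeric(fs * 2)
  x[500 + seq_along(tri)] <- -tri
  rec <- recording(x, fs)
  m <- measure_spike(rec, (500 + n / 2) / fs, window = 0.06)
  expect_equal(m$width, base / 2, tolerance = 0.1)
  expect_equal(m$amplitude, 1, tolerance = 1e-6)
})

test_that("measured amplitude tracks the inserted spike height", {
  fs <- 500
  withr::with_seed(7, {
    x <- rnorm(fs * 30)
    sdr <- mad(x)
    x <- ictaloop:::insert_waveforms(x, 15, spike_waveform(0.04, 8 * sdr, fs),
                                     fs)
    rec <- bandpass_filter(recording(x, fs), c(5, 40))
    m <- measure_spike(rec, 15, window = 0.06)
    expect_equal(m$amplitude, 8 * sdr, tolerance = 0.15 * 8 * sdr)
  })
})

test_that("a flat window measures zero and fails the width flag", {
  rec <- recording(rep(0, 1000), 500)
  m <- measure_spike(rec, 1)
  expect_equal(m$amplitude, 0)
  expect_equal(m$width, 0)
})

test_that("template matching scores identity at 1 and negation at -1", {
  fs <- 500
  wf <- spike_waveform(0.04, 3, fs)
  x <- numeric(fs * 2)
  i0 <- 500
  x[i0:(i0 + length(wf) - 1)] <- wf
  rec <- recording(x, fs)
  t_peak <- (i0 + which.min(wf) - 2) / fs
  expect_equal(template_match(rec, t_peak, wf), 1, tolerance = 1e-9)
  expect_equal(template_match(rec, t_peak, -wf), -1, tolerance = 1e-9)
})

test_that("generated spikes at SNR 8 match their waveform above 0.8", {
  cfg <- gen_config(duration = 20, seed = 3, interictal_rate = 0.3,
                    seizure_rate = 0, spike_amplitude = 8)
  s <- generate_lfp(cfg)
  filt <- bandpass_filter(s$recording, c(5, 40))
  wf <- spike_waveform(0.04, 8, 500)
  sc <- vapply(s$truth$interictal_spike_times, function(t)
    template_match(filt, t, wf), 0)
  expect_gt(length(sc), 2)
  expect_true(all(sc > 0.8))
})

test_that("artifact veto flags events near clipping, closed at the boundary", {
  fs <- 500
  x <- rnorm(fs * 20)
  t <- (seq_along(x) - 1) / fs
  x[t >= 10 & t < 10.2] <- 50                  # clipping segment
  rec <- recording(x, fs)
  ev <- data.frame(time = c(2, 9.6, 10.1, 10.65, 15))
  crit <- artifact_criteria(saturation_level = 49, veto_pad = 0.5)
  out <- reject_artifacts(rec, ev, crit)
  expect_equal(out$artifact, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  # event exactly veto_pad away from an artifact sample is still flagged
  ev2 <- data.frame(time = 10 - 0.5)
  expect_true(reject_artifacts(rec, ev2, crit)$artifact)
  # no saturation and no broadband veto -> no flags
  out0 <- reject_artifacts(recording(rnorm(fs * 5), fs), ev,
                           artifact_criteria())
  expect_false(any(out0$artifact))
})

test_that("Boolean combination matches the truth-table oracle", {
  rule <- "amplitude AND NOT artifact"
  ev <- data.frame(time = 1:4,
                   amplitude = c(TRUE, TRUE, FALSE, FALSE),
                   artifact = c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(combine_criteria(ev, rule)$time, 1)
  expect_equal(combine_criteria(ev, rule), bf_combine(ev, rule))

  withr::with_seed(11, {
    for (i in 1:20) {
      ev <- data.frame(time = 1:16,
                       a = sample(c(TRUE, FALSE), 16, TRUE),
                       b = sample(c(TRUE, FALSE), 16, TRUE),
                       c = sample(c(TRUE, FALSE), 16, TRUE))
      for (rule in c("a AND (b OR c)", "NOT (a OR b)",
                     "(a AND b) OR (NOT c)", "a OR b OR NOT (a AND c)")) {
        expect_equal(combine_criteria(ev, rule), bf_combine(ev, rule),
                     info = rule)
      }
      # De Morgan identity
      expect_equal(combine_criteria(ev, "NOT (a OR b)"),
                   combine_criteria(ev, "(NOT a) AND (NOT b)"))
    }
  })
})

test_that("rules with undefined flags or foreign syntax are rejected", {
  ev <- data.frame(time = 1, a = TRUE)
  expect_error(combine_criteria(ev, "a AND ghost"), "undefined")
  expect_error(combine_criteria(ev, "a + 1"), "AND/OR/NOT")
})

test_that("detection is invariant to signal scaling", {
  cfg <- gen_config(duration = 60, seed = 13)
  s <- generate_lfp(cfg)
  a <- detect_spikes(s$recording)
  scaled <- recording(s$recording$samples * 7.3, 500)
  b <- detect_spikes(scaled)
  expect_equal(a$time, b$time)
})

test_that("default criteria reach high sensitivity at low false rates", {
  cfg <- gen_config(duration = 120, seed = 29)
  s <- generate_lfp(cfg)
  sp <- detect_spikes(s$recording)
  truth <- sort(c(s$truth$interictal_spike_times,
                  unlist(s$truth$per_seizure_spike_times)))
  m <- match_events(sp$time, truth)
  expect_gte(m$sensitivity, 0.95)
  expect_lte(m$n_false / (120 / 60), 2)
  # accepted events strictly increasing, none closer than the refractory
  expect_false(is.unsorted(sp$time, strictly = TRUE))
  expect_true(all(diff(sp$time) >= spike_criteria()$refractory - 1e-9))
})
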