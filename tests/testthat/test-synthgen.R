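test_that("zero rates give a pure-noise recording with empty truth", {
  cfg <- gen_config(duration = 20, interictal_rate = 0, seizure_rate = 0,
                    seed = 5)
  s <- generate_lfp(cfg)
  expect_length(s$truth$interictal_spike_times, 0)
  expect_equal(nrow(s$truth$seizure_intervals), 0)
  expect_equal(nrow(s$recording$samples), 20 * 500)
  # noise only: robust SD near the configured sigma
  expect_equal(mad(s$recording$samples[, 1]), 1, tolerance = 0.05)
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- gen_config(duration = 30, seed = 77)
  a <- generate_lfp(cfg)
  b <- generate_lfp(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$truth, b$truth)
  # different seed differs
  c <- generate_lfp(gen_config(duration = 30, seed = 78))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("interictal counts follow the Poisson expectation across seeds", {
  counts <- vapply(1:50, function(k) {
    cfg <- gen_config(duration = 600, interictal_rate = 0.2,
                      seizure_rate = 0, seed = k)
    length(generate_lfp(cfg)$truth$interictal_spike_times)
  }, 0)
  lambda <- 0.2 * 600
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 50))
})

test_that("removing every inserted waveform recovers the pure-noise signal", {
  cfg <- gen_config(duration = 60, seed = 21, interictal_rate = 0.2,
                    seizure_rate = 0.03)
  s <- generate_lfp(cfg)
  noise <- generate_lfp(gen_config(duration = 60, seed = 21,
                                   interictal_rate = 0, seizure_rate = 0))
  wf <- spike_waveform(cfg$spike_width, cfg$spike_amplitude, 500)
  ev <- c(s$truth$interictal_spike_times,
          unlist(s$truth$per_seizure_spike_times))
  expect_gt(length(ev), 0)
  x <- ictaloop:::insert_waveforms(s$recording$samples[, 1], ev, wf, 500,
                                   scale = -1)
  expect_equal(x, noise$recording$samples[, 1], tolerance = 1e-12)
})

test_that("seizure truth intervals are disjoint and contain their spikes", {
  for (seed in 1:5) {
    s <- generate_lfp(gen_config(duration = 400, seed = seed,
                                 seizure_rate = 0.02))
    iv <- s$truth$seizure_intervals
    if (nrow(iv) > 1)
      expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))
    for (k in seq_len(nrow(iv))) {
      sp <- s$truth$per_seizure_spike_times[[k]]
      expect_true(all(sp >= iv[k, 1] & sp < iv[k, 2]))
      expect_false(is.unsorted(sp, strictly = TRUE))
      expect_true(all(diff(sp) < 1))       # cluster rule holds by construction
    }
  }
})

test_that("intervention truncation follows the post-trigger arithmetic", {
  s <- make_toy_session(seizure = c(10, 20))
  out <- apply_intervention(s, trigger_times = 12, truncation_factor = 0.5,
                            config = gen_config())
  expect_equal(unname(out$truth$seizure_intervals[1, 2]), 16)  # 8 s -> 4 s after trigger
  expect_true(all(out$truth$per_seizure_spike_times[[1]] < 16))
  expect_equal(out$truth$light_intervals[1, ], c(on = 12, off = 16))
  # waveforms of dropped spikes removed from the signal: beyond 16 s + edge,
  # the signal is exactly the background (zero)
  i0 <- 17 * 500; i1 <- 19 * 500
  expect_equal(max(abs(out$recording$samples[i0:i1, 1])), 0)
})

test_that("factor 1 intervention is the identity apart from the light log", {
  s <- make_toy_session()
  out <- apply_intervention(s, 12, 1, gen_config())
  expect_identical(out$recording$samples, s$recording$samples)
  expect_equal(out$truth$seizure_intervals, s$truth$seizure_intervals)
  expect_equal(out$truth$per_seizure_spike_times,
               s$truth$per_seizure_spike_times)
})

test_that("triggers outside every seizure warn and change nothing", {
  s <- make_toy_session()
  expect_warning(out <- apply_intervention(s, 35, 0.5, gen_config()),
                 "outside")
  expect_equal(out$truth$seizure_intervals, s$truth$seizure_intervals)
  expect_identical(out$recording$samples, s$recording$samples)
})

test_that("lengthening factors are rejected", {
  s <- make_toy_session()
  expect_error(apply_intervention(s, 12, 1.5, gen_config()), "not modeled")
  expect_error(gen_config(truncation_factor = 1.5), "truncation_factor")
})

test_that("calcium traces are flat at baseline without events or noise", {
  truth <- list(interictal_spike_times = numeric(0),
                seizure_intervals = matrix(numeric(0), ncol = 2),
                per_seizure_spike_times = list())
  ca <- generate_calcium(truth, 3, gen_config(duration = 10,
                                              ca_noise_sigma = 0))
  expect_true(all(ca$traces == 1))
})

test_that("a single spike yields a delayed peak with monotone decay", {
  truth <- list(interictal_spike_times = 5,
                seizure_intervals = matrix(numeric(0), ncol = 2),
                per_seizure_spike_times = list())
  ca <- generate_calcium(truth, 1, gen_config(duration = 20,
                                              ca_noise_sigma = 0))
  tr <- ca$traces[1, ]
  pk <- which.max(tr)
  expect_gt(ca$frame_times[pk], 5)
  expect_true(all(diff(tr[pk:(pk + 30)]) <= 1e-12))
})

test_that("invalid kernel time constants are rejected", {
  expect_error(gen_config(rise_tau = 0.5, decay_tau = 0.1), "decay_tau")
})

test_that("seeg generator honors involvement and latency rules", {
  plan <- data.frame(channel = c("fc1", "ah1"), region = c("FC", "AH"))
  # full involvement, zero latency spread -> simultaneous onsets
  rule <- list(FC = list(latency_mean = 0, latency_sd = 0, involvement_prob = 1),
               AH = list(latency_mean = 0, latency_sd = 0, involvement_prob = 1))
  case <- generate_seeg_case(4, plan, rule,
                             gen_config(sampling_rate = 1000, seed = 3),
                             spacing = 5, seizure_duration = 2)
  on <- case$onsets
  for (s in unique(on$seizure)) {
    ts <- on$onset_time[on$seizure == s]
    expect_equal(ts[1], ts[2])
  }
  expect_equal(ncol(case$recording$samples), 2)
  expect_equal(case$recording$sampling_rate, 1000)
})

test_that("empirical seeg involvement matches its probability across seeds", {
  plan <- data.frame(channel = c("fc1", "ah1"), region = c("FC", "AH"))
  rule <- list(FC = list(latency_mean = 0.2, latency_sd = 0.02,
                         involvement_prob = 15 / 18),
               AH = list(latency_mean = 0, latency_sd = 0.02,
                         involvement_prob = 1))
  fr <- vapply(1:40, function(k) {
    case <- generate_seeg_case(18, plan, rule,
                               gen_config(sampling_rate = 1000, seed = k),
                               spacing = 4, seizure_duration = 1.5)
    involvement_fraction(case$onsets, "FC")$fraction
  }, 0)
  # mean involvement ~ 83% within binomial sampling error of the seed sweep
  se <- 100 * sqrt((15 / 18) * (3 / 18) / (18 * 40))
  expect_lt(abs(mean(fr) - 100 * 15 / 18), 3 * se)
})

test_that("too-short sessions are flagged rather than failing", {
  cfg <- gen_config(duration = 1.2, seizure_rate = 0.5, interictal_rate = 0)
  s <- generate_lfp(cfg)
  expect_true(s$truth$no_seizures_possible)
  expect_equal(nrow(s$truth$seizure_intervals), 0)
})
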