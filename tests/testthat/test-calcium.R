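test_that("trace extraction averages ROI pixels and is local and linear", {
  movie <- array(2.5, dim = c(10, 8, 8))
  masks <- matrix(0L, 8, 8)
  masks[2:3, 2:3] <- 1L
  masks[6:7, 6:7] <- 2L
  tr <- extract_traces(movie, masks)
  expect_true(all(tr == 2.5))
  # two disjoint blobs: swapping blob intensities swaps traces
  m2 <- movie
  m2[, 2:3, 2:3] <- 1
  m2[, 6:7, 6:7] <- 9
  tr2 <- extract_traces(m2, masks)
  m3 <- movie
  m3[, 2:3, 2:3] <- 9
  m3[, 6:7, 6:7] <- 1
  tr3 <- extract_traces(m3, masks)
  expect_equal(tr2[1, ], tr3[2, ])
  expect_equal(tr2[2, ], tr3[1, ])
  # linearity
  expect_equal(extract_traces(2 * m2, masks), 2 * tr2)
  expect_error(extract_traces(movie, matrix(0L, 8, 8)), "no ROI")
})

test_that("movie rendering round-trips the generating traces exactly", {
  cfg <- gen_config(duration = 40, seed = 4, ca_noise_sigma = 0.05)
  s <- generate_lfp(cfg)
  ca <- generate_calcium(s$truth, 6, cfg)
  mv <- render_calcium_movie(ca$traces, frame_dim = c(24, 24), radius = 2,
                             pixel_noise = 0)
  rt <- extract_traces(mv$movie, mv$masks)
  expect_lt(max(abs(rt - ca$traces) / pmax(abs(ca$traces), 1e-12)), 1e-6)
})

test_that("dF/F is zero for constant input and invariant to gain", {
  ft <- seq(0, 60, by = 1 / 15.49)
  const <- rep(4, length(ft))
  expect_true(all(compute_dff(const, ft)$dff == 0))
  withr::with_seed(5, {
    tr <- 2 + abs(rnorm(length(ft), sd = 0.1))
    a <- compute_dff(tr, ft)$dff
    b <- compute_dff(7 * tr, ft)$dff
    expect_equal(a, b, tolerance = 1e-12)
  })
})

test_that("a brief step on a unit baseline gives peak dF/F near 1", {
  ft <- seq(0, 120, by = 1 / 15.49)
  tr <- rep(1, length(ft))
  tr[ft >= 60 & ft < 62] <- 2                  # 2 s step << 30 s window
  d <- compute_dff(tr, ft)
  expect_equal(max(d$dff), 1, tolerance = 0.02)
  expect_equal(d$baseline[ft >= 55 & ft <= 58], rep(1, sum(ft >= 55 & ft <= 58)))
})

test_that("nonpositive baselines are rejected with a message", {
  ft <- seq(0, 60, by = 1 / 15.49)
  expect_error(compute_dff(rep(0, length(ft)), ft), "baseline")
})

test_that("max-normalization hits 1, preserves order and is idempotent", {
  withr::with_seed(8, v <- abs(rnorm(200)) + 0.1)
  nv <- normalize_to_max(v)
  expect_equal(max(nv), 1)
  expect_equal(order(v), order(nv))
  expect_equal(normalize_to_max(nv), nv)
  expect_warning(out <- normalize_to_max(c(-2, -1)), "dropped")
  expect_null(out)
})

test_that("peri-event alignment matches the brute-force loop", {
  withr::with_seed(12, {
    ft <- seq(0, 50, by = 1 / 15.49)
    dff <- matrix(rnorm(3 * length(ft)), nrow = 3)
    evs <- c(4.2, 17.9, 33.3, 49.5)              # last event clipped
    pe <- align_to_events(dff, ft, evs, pre = 2, post = 2, bin = 0.2)
    ref <- bf_peri_event(dff, ft, evs, 2, 2, 0.2)
    expect_equal(pe$values, ref, tolerance = 1e-12)
    expect_true(0 %in% pe$bin_centers)
  })
  expect_error(align_to_events(matrix(0, 1, 10), seq(0, 9), 100, 1, 1),
               "no usable events")
})

test_that("events on flat traces give an all-zero matrix", {
  ft <- seq(0, 20, by = 1 / 15.49)
  pe <- align_to_events(matrix(0, 2, length(ft)), ft, c(5, 10), 2, 2)
  expect_true(all(pe$values == 0))
})

test_that("spike-aligned activity rises after time zero on synthetic data", {
  cfg <- gen_config(duration = 300, seed = 9)
  s <- generate_lfp(cfg)
  ca <- generate_calcium(s$truth, 12, cfg)
  dffm <- t(apply(ca$traces, 1, function(v)
    normalize_to_max(compute_dff(v, ca$frame_times)$dff)))
  pe <- align_to_events(dffm, ca$frame_times,
                        s$truth$interictal_spike_times, pre = 3, post = 3)
  post_i <- pe$bin_centers >= 0 & pe$bin_centers <= 1
  pre_i <- pe$bin_centers >= -2 & pe$bin_centers <= -1
  rising <- rowMeans(pe$values[, post_i]) > rowMeans(pe$values[, pre_i])
  expect_gte(mean(rising), 0.9)
  # the grand-average peak sits at or after the event
  cm <- colMeans(pe$values)
  expect_gte(pe$bin_centers[which.max(cm)], 0)
})

test_that("seizure-end-aligned activity decays after time zero", {
  cfg <- gen_config(duration = 300, seed = 9)
  s <- generate_lfp(cfg)
  ca <- generate_calcium(s$truth, 12, cfg)
  dffm <- t(apply(ca$traces, 1, function(v)
    normalize_to_max(compute_dff(v, ca$frame_times)$dff)))
  pe <- align_to_events(dffm, ca$frame_times,
                        s$truth$seizure_intervals[, 2], pre = 3, post = 3)
  cm <- colMeans(pe$values)
  at0 <- cm[which.min(abs(pe$bin_centers))]
  at2 <- cm[which.min(abs(pe$bin_centers - 2))]
  expect_lt(at2, at0)
})

test_that("correlation is 1 against itself and null under shuffling", {
  ft <- seq(0, 100, by = 1 / 15.49)
  withr::with_seed(3, sp <- sort(runif(150, 0, 100)))
  rate_bin <- 1 / 15.49
  breaks <- seq(ft[1], ft[length(ft)] + rate_bin, by = rate_bin)
  counts <- tabulate(findInterval(sp, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  rate <- counts / rate_bin
  mids <- head(breaks, -1) + rate_bin / 2
  rate_f <- approx(mids, rate, xout = ft, rule = 2)$y
  self <- activity_spiking_correlation(matrix(rate_f, 1), ft, sp)
  expect_equal(unname(self$r[1]), 1, tolerance = 1e-9)

  # permutation null on a real synthetic session: |mean r| under shuffled
  # spike times stays below the permutation 95% bound around 0
  cfg <- gen_config(duration = 120, seed = 14)
  s <- generate_lfp(cfg)
  ca <- generate_calcium(s$truth, 6, cfg)
  dffm <- t(apply(ca$traces, 1, function(v)
    normalize_to_max(compute_dff(v, ca$frame_times)$dff)))
  allsp <- sort(c(s$truth$interictal_spike_times,
                  unlist(s$truth$per_seizure_spike_times)))
  obs <- activity_spiking_correlation(dffm, ca$frame_times, allsp)$mean_r
  withr::with_seed(6, {
    perm <- replicate(100, activity_spiking_correlation(
      dffm, ca$frame_times, sort(runif(length(allsp), 0, 120)))$mean_r)
  })
  expect_lt(abs(mean(perm)), 0.05)
  expect_gt(obs, quantile(abs(perm), 0.95))
})

test_that("zero-variance cells are excluded from the correlation", {
  ft <- seq(0, 20, by = 1 / 15.49)
  dff <- rbind(rep(0, length(ft)), rnorm(length(ft)))
  out <- activity_spiking_correlation(dff, ft, c(5, 6, 12))
  expect_true(is.na(out$r[1]))
  expect_equal(out$n_cells, 1)
})
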