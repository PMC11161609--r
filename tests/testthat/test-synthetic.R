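# Synthetic generator: waveform morphology, determinism, spectral
# placement and the observation model.

test_that("noiseless 60-BPM waveform has exactly 10 systolic peaks at 1-s spacing", {
  cf <- synth_config(duration_s = 10, hr_bpm = 60, hrv_sd_bpm = 0,
                     noise_sd = 0, seed = 7)
  p <- simulate_ppg(cf)
  expect_length(p$meta$systolic_peaks, 10)
  expect_equal(diff(p$meta$systolic_peaks), rep(1, 9), tolerance = 1e-9)
  # systolic maxima visible in the samples themselves
  s <- p$samples
  loc <- which(diff(sign(diff(s))) == -2) + 1
  expect_equal(sum(s[loc] > 0.7), 10)
  expect_equal(max(s), 1)   # unit peak amplitude
})

test_that("identical config and seed reproduce bit-identical samples", {
  cf <- synth_config(duration_s = 8, hr_bpm = 80, seed = 7)
  a <- simulate_ppg(cf)
  b <- simulate_ppg(cf)
  expect_identical(a$samples, b$samples)
  ra <- simulate_rgb_trace(a, cf)
  rb <- simulate_rgb_trace(b, cf)
  expect_identical(ra$values, rb$values)
  expect_identical(serialize(ra$values, NULL), serialize(rb$values, NULL))
})

test_that("dominant PSD peak of the noiseless waveform sits at the configured rate", {
  for (hr in c(55, 90, 150)) {
    cf <- synth_config(duration_s = 20, hr_bpm = hr, hrv_sd_bpm = 0,
                       noise_sd = 0, seed = 1)
    est <- estimate_hr_welch(simulate_ppg(cf))
    bin_bpm <- 60 * cf$cppg_rate / 4096
    expect_lt(abs(est - hr), bin_bpm + 1e-9)
  }
})

test_that("generator rejects invalid configuration naming the field", {
  expect_error(synth_config(hr_bpm = 300), "hr_bpm")
  expect_error(synth_config(hr_bpm = 140, fps = 4), "fps")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(diastolic_delay_frac = 1.2), "diastolic_delay_frac")
  expect_error(synth_config(activity_label = "sprint"), "activity_label")
})

test_that("zero pulsatile gains leave no in-band chrominance signal", {
  cf <- synth_config(duration_s = 15, hr_bpm = 70, noise_sd = 0,
                     pulsatile_gains = c(0, 0, 0), wander_amp = 0.03,
                     illum_drift_amp = 0.02, seed = 11)
  ppg <- simulate_ppg(cf)
  rgb <- simulate_rgb_trace(ppg, cf)
  in_var <- var(rgb$values[, "G"])
  expect_lt(var(extract_chrom(rgb)$samples), 1e-12 * in_var)
  expect_lt(var(extract_pos(rgb)$samples), 1e-12 * in_var)
})

test_that("inverted green channel tracks the generating pulse", {
  fx <- clean_pulsatile(hr_bpm = 72, seed = 3)
  g <- bandpass_signal(detrend_signal(extract_green(fx$rgb)))
  n <- min(length(g$samples), length(fx$ref$samples))
  expect_gt(pearson_r(g$samples[1:n], fx$ref$samples[1:n]), 0.95)
})

test_that("frame rendering round-trips through patch extraction at zero pixel noise", {
  cf <- synth_config(duration_s = 2, hr_bpm = 70, seed = 5)
  ppg <- simulate_ppg(cf)
  rgb <- simulate_rgb_trace(ppg, cf)
  fr <- simulate_frames(rgb, cf, size = 64, pixel_noise_sd = 0)
  map <- extract_patch_means(fr$frames, fr$coords, fps = cf$fps,
                             landmark_ids = fr$landmark_ids,
                             region_map = fr$region_map)
  for (l in seq_along(fr$landmark_ids))
    expect_equal(map$values[l, , ], rgb$values, ignore_attr = TRUE)
})

test_that("motion activities translate landmarks over time, staying in frame", {
  cf <- activity_preset("rotation", duration_s = 2, seed = 5)
  rgb <- simulate_rgb_trace(simulate_ppg(cf), cf)
  fr <- simulate_frames(rgb, cf, size = 64)
  moved <- apply(fr$coords[, 1, ], 2, function(v) max(v) - min(v))
  expect_true(any(moved > 0))
  half <- 15
  expect_true(all(fr$coords[, , 1] - half >= 0))
  expect_true(all(fr$coords[, , 1] + half <= 63))
  expect_true(all(fr$coords[, , 2] - half >= 0))
  expect_true(all(fr$coords[, , 2] + half <= 63))
  # rest keeps landmarks static
  cf2 <- activity_preset("rest", duration_s = 2, seed = 5)
  fr2 <- simulate_frames(simulate_rgb_trace(simulate_ppg(cf2), cf2), cf2)
  expect_equal(max(apply(fr2$coords[, 1, ], 2, function(v) max(v) - min(v))), 0)
})

test_that("make_dataset keeps per-sample provenance and window arithmetic", {
  cfgs <- lapply(1:6, function(i)
    synth_config(duration_s = 10, hr_bpm = 70, seed = i))
  d <- make_dataset(cfgs)
  expect_length(d, 6)
  for (smp in d) {
    wins <- segment_windows(
      pulse_signal(smp$rgb$values[, "G"], rate = smp$rgb$fps), 10)
    expect_length(wins, 1)
    expect_length(wins[[1]]$samples, 300)
  }
  expect_error(make_dataset(list()), "non-empty")
  # mixed frame rates preserved per sample
  d2 <- make_dataset(list(synth_config(duration_s = 10, fps = 25, seed = 1),
                          synth_config(duration_s = 10, fps = 30, seed = 2)))
  expect_equal(vapply(d2, function(s) s$rgb$fps, numeric(1)), c(25, 30))
  expect_message(make_dataset(list(synth_config(seed = 1),
                                   synth_config(seed = 1))), "duplicate")
})
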