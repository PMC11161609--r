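# Classical extractors: invariances, degenerate rules, pulse recovery
# and heart-rate preservation.

intensity_trace <- function(depth = 0.01, base = 0.5) {
  t <- (0:299) / 30
  m <- depth * sin(2 * pi * 1.5 * t)
  rgb_trace(cbind(1 + m, 1 + m, 1 + m) * base, fps = 30)
}

test_that("CHROM and POS cancel pure intensity modulation", {
  tr <- intensity_trace()
  scale_ref <- sd(tr$values[, "G"])
  expect_lt(max(abs(extract_chrom(tr)$samples)), 1e-9 * scale_ref)
  expect_lt(max(abs(extract_pos(tr)$samples)), 1e-9 * scale_ref)
})

test_that("CHROM, POS and LGI are invariant to a global gain", {
  fx <- clean_pulsatile(seed = 5, noise_sd = 0.001)
  tr <- fx$rgb
  tr2 <- tr
  tr2$values <- tr$values * 3.7
  for (fn in list(extract_chrom, extract_pos, extract_lgi)) {
    a <- fn(tr)$samples
    b <- fn(tr2)$samples
    expect_lt(max(abs(a - b)), 1e-9 * (sd(a) + 1e-30))
  }
})

test_that("degenerate extractor inputs follow their stated rules", {
  t0 <- (0:99) / 30
  # constant green -> zero green output
  tr <- rgb_trace(cbind(1 + 0.1 * sin(t0), rep(0.5, 100), 1 + cos(t0)),
                  fps = 30)
  expect_true(all(extract_green(tr)$samples == 0))
  # green isolates its channel: R and B have no influence
  g <- 0.5 + 0.01 * sin(2 * pi * 1.1 * t0)
  trA <- rgb_trace(cbind(runif(100, 0.4, 0.6), g, runif(100, 0.4, 0.6)),
                   fps = 30)
  trB <- rgb_trace(cbind(runif(100, 0.1, 0.9), g, runif(100, 0.1, 0.9)),
                   fps = 30)
  expect_equal(extract_green(trA)$samples, extract_green(trB)$samples)
  # non-positive channel mean rejected
  bad <- rgb_trace(cbind(sin(2 * pi * 1.5 * t0) - 0.5,
                         1 + 0.1 * sin(t0), 1 + 0.1 * cos(t0)), fps = 30)
  expect_error(extract_chrom(bad), "positive")
  # rank-1 data projects to zero under LGI
  u <- c(1, 2, 3)
  s <- sin(2 * pi * 1.3 * t0)
  rank1 <- rgb_trace(outer(s, u) + 5, fps = 30)
  expect_lt(max(abs(extract_lgi(rank1)$samples)), 1e-9)
})

test_that("LGI output is stable under a rotation of colour space", {
  # rank-2 data: a dominant intensity direction plus a weak pulse along an
  # orthogonal colour axis; the orthogonal projection isolates the pulse
  t0 <- (0:299) / 30
  u0 <- c(2, 1, 1) / sqrt(6)
  v <- c(1, -2, 0) / sqrt(5)                 # orthogonal to u0
  intensity <- sin(2 * pi * 0.3 * t0)
  pulse <- sin(2 * pi * 1.4 * t0)
  vals <- 5 + outer(intensity, u0) + 0.05 * outer(pulse, v)
  colnames(vals) <- c("R", "G", "B")
  tr <- rgb_trace(vals, fps = 30)
  Q <- qr.Q(qr(matrix(c(1, 2, 3, 0, 1, 4, 5, 6, 0), 3, 3)))
  tr2 <- tr
  tr2$values <- tr$values %*% t(Q)
  colnames(tr2$values) <- c("R", "G", "B")
  a <- extract_lgi(tr)$samples
  b <- extract_lgi(tr2)$samples
  expect_gt(abs(cor(a, b)), 1 - 1e-6)
  expect_equal(sd(b) / sd(a), 1, tolerance = 1e-6)
  expect_gt(abs(cor(a, pulse)), 1 - 1e-4)
})

test_that("every extractor recovers a clean pulse", {
  fx <- clean_pulsatile(hr_bpm = 72, seed = 3)
  ref <- fx$ref$samples
  thresholds <- c(chrom = 0.9, pos = 0.9, lgi = 0.8, ica = 0.9)
  for (m in names(thresholds)) {
    fn <- rppg_extractors()[[m]]
    s <- bandpass_signal(detrend_signal(fn(fx$rgb)))$samples
    n <- min(length(s), length(ref))
    expect_gt(abs(pearson_r(s[1:n], ref[1:n])), thresholds[[m]])
  }
})

test_that("ICA recovers the pulse from a known mixing and is deterministic", {
  set.seed(42)
  t0 <- (0:599) / 30
  pulse <- sin(2 * pi * 1.3 * t0) + 0.3 * sin(2 * pi * 2.6 * t0)
  wander <- sin(2 * pi * 0.3 * t0 + 1)
  noise <- rnorm(600)
  A <- matrix(c(0.04, 0.08, 0.05,
                0.06, 0.05, 0.07,
                0.01, 0.012, 0.009), 3, 3)
  mixed <- cbind(pulse, wander, noise) %*% t(A)
  tr <- rgb_trace(sweep(mixed, 2, c(1, 1, 1), `+`), fps = 30)
  out <- extract_ica(tr, seed = 1)
  expect_gt(abs(pearson_r(out$samples, pulse)), 0.95)
  out2 <- extract_ica(tr, seed = 1)
  expect_identical(out$samples, out2$samples)
})

test_that("all methods preserve heart rate within one Welch bin across the band", {
  hrs <- c(40, 70, 100, 140, 180, 220)
  bin_bpm <- 60 * 30 / 4096
  for (hr in hrs) {
    fx <- clean_pulsatile(hr_bpm = hr, duration_s = 20, seed = hr,
                          noise_sd = 0, wander_amp = 0, hrv_sd_bpm = 0)
    for (m in c("green", "chrom", "pos", "lgi", "ica")) {
      s <- rppg_extractors()[[m]](fx$rgb)
      expect_lt(abs(estimate_hr_welch(s) - hr), bin_bpm + 1e-9,
                label = sprintf("%s at %d BPM", m, hr))
    }
  }
  # a 25-fps acquisition behaves the same
  cf25 <- synth_config(duration_s = 20, fps = 25, hr_bpm = 80,
                       hrv_sd_bpm = 0, noise_sd = 0, wander_amp = 0, seed = 2)
  rgb <- simulate_rgb_trace(simulate_ppg(cf25), cf25)
  expect_lt(abs(estimate_hr_welch(extract_chrom(rgb)) - 80),
            60 * 25 / 4096 + 1e-9)
})

test_that("extract_all stacks the four input methods in fixed order", {
  fx <- clean_pulsatile(seed = 9, duration_s = 10)
  stack <- extract_all(fx$rgb)
  expect_equal(colnames(stack), c("ica", "lgi", "chrom", "pos"))
  expect_equal(nrow(stack), nrow(fx$rgb$values))
  stack2 <- extract_all(fx$rgb)
  expect_identical(stack, stack2)
  expect_error(extract_all(fx$rgb, methods = c("ica", "grgb")), "grgb")
  # failures propagate with the method name
  t0 <- (0:99) / 30
  bad <- rgb_trace(cbind(sin(2 * pi * 1.5 * t0) - 0.5,
                         1 + 0.1 * sin(t0), 1 + 0.1 * cos(t0)), fps = 30)
  expect_error(extract_all(bad, methods = "chrom"), "chrom")
})
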