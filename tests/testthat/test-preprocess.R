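# Conditioning chain: detrend, bandpass, resampling, variance rejection,
# equalization, windowing, normalization.

test_that("linear detrend removes lines exactly and is linear", {
  t <- 1:200
  expect_equal(detrend_signal(2.5 * t + 7), rep(0, 200), tolerance = 1e-9)
  # a cosine centred on the sampling window over whole periods is exactly
  # mean- and trend-free, so it passes through unchanged
  k <- 0:299
  s <- cos(2 * pi * 1.5 * (k - 149.5) / 30)
  expect_equal(detrend_signal(s), s, tolerance = 1e-9)
  # a plain sine keeps its shape up to the small discrete-sampling trend
  s2 <- sine_pulse(1.5, rate = 30, dur = 10)
  expect_gt(cor(detrend_signal(s2), s2), 0.995)
  x <- rnorm(200)
  expect_equal(detrend_signal(x + 0.3 * t - 2), detrend_signal(x),
               tolerance = 1e-9)
  expect_lt(abs(mean(detrend_signal(x))), 1e-9 * sd(x))
})

test_that("bandpass magnitude response matches the heart-rate band", {
  rate <- 30
  amp_of <- function(hz) {
    x <- sine_pulse(hz, rate = rate, dur = 30)
    y <- bandpass_signal(x, rate = rate)
    core <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
    sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2))
  }
  for (hz in c(1, 2, 3)) expect_gt(amp_of(hz), 0.95)
  expect_lt(amp_of(0.1), 0.05)
  expect_lt(amp_of(7), 0.05)
})

test_that("bandpass is zero-phase and removes DC", {
  x <- sine_pulse(2, rate = 30, dur = 20)
  y <- bandpass_signal(x, rate = 30)
  core <- 100:500
  cc <- sapply(-5:5, function(lag)
    cor(x[core], y[core + lag]))
  expect_equal((-5:5)[which.max(cc)], 0)
  expect_gt(max(cc), 0.999)
  z <- bandpass_signal(x + 10, rate = 30)
  expect_lt(abs(mean(z)), 1e-3 * 10)   # relative to the 10-unit offset
  expect_error(bandpass_signal(x, rate = 7), "resample")
})

test_that("cubic resampling is accurate on band-limited signals", {
  s60 <- pulse_signal(sine_pulse(1, rate = 60, dur = 10), rate = 60)
  s30 <- resample_to(s60, 30)
  truth <- sine_pulse(1, rate = 30, dur = 10)[seq_along(s30$samples)]
  expect_lt(max(abs(s30$samples - truth)), 1e-3)
  expect_equal(s30$rate, 30)
  # identity at own rate
  same <- resample_to(s60, 60)
  expect_equal(same$samples, s60$samples, tolerance = 1e-12)
  # constant stays constant
  cn <- resample_to(pulse_signal(rep(2, 120), rate = 60), 30)
  expect_equal(cn$samples, rep(2, length(cn$samples)), tolerance = 1e-12)
})

test_that("windowing keeps full non-overlapping windows only", {
  s <- pulse_signal(rnorm(35 * 30), rate = 30)
  w <- segment_windows(s, 10)
  expect_length(w, 3)
  expect_true(all(vapply(w, function(x) length(x$samples), numeric(1)) == 300))
  expect_equal(attr(w, "discarded_samples"), 150)
  expect_identical(unlist(lapply(w, `[[`, "samples")), s$samples[1:900])
  expect_length(segment_windows(pulse_signal(rnorm(300), rate = 30), 10), 1)
  expect_error(segment_windows(pulse_signal(rnorm(297), rate = 30), 10),
               "shorter")
})

test_that("min-max normalization maps to [0,1] with a degenerate rule", {
  r <- minmax_normalize(c(2, 4, 6))
  expect_equal(r$samples, c(0, 0.5, 1))
  expect_equal(c(r$min, r$max), c(2, 6))
  cn <- minmax_normalize(rep(3, 10))
  expect_true(cn$degenerate)
  expect_equal(cn$samples, rep(0.5, 10))
  x <- rnorm(100)
  rx <- minmax_normalize(x)$samples
  expect_true(all(rx >= 0 & rx <= 1))
})

test_that("histogram equalization is monotone, idempotent and handles constants", {
  vals <- array(rnorm(30 * 50 * 3), dim = c(30, 50, 3))
  map <- st_map(vals, fps = 30, landmark_ids = 1:30,
                region_map = list(face = 1:30))
  eq <- equalize_histogram(map)
  for (ch in 1:3) {
    a <- as.vector(vals[, , ch]); b <- as.vector(eq$values[, , ch])
    expect_true(all(b >= 0 & b <= 255))
    ord <- order(a)
    expect_true(all(diff(b[ord]) >= 0))
  }
  # distinct values spread uniformly -> second pass changes almost nothing
  eq2 <- equalize_histogram(eq)
  expect_lt(max(abs(eq2$values - eq$values)), 1.5)
  # already-uniform input is an affine rescale
  u <- array(seq(0, 1, length.out = 30 * 20 * 3), dim = c(30, 20, 3))
  equ <- equalize_histogram(st_map(u, fps = 30, landmark_ids = 1:30,
                                   region_map = list(face = 1:30)))
  for (ch in 1:3) {
    fit <- lm(as.vector(equ$values[, , ch]) ~ as.vector(u[, , ch]))
    expect_gt(summary(fit)$r.squared, 0.9999)
  }
  cn <- array(5, dim = c(3, 4, 3))
  eqc <- equalize_histogram(st_map(cn, fps = 30, landmark_ids = 1:3,
                                   region_map = list(face = 1:3)))
  expect_equal(length(unique(as.vector(eqc$values))), 1)
})

test_that("low-variance rejection drops dead landmarks", {
  n_lm <- 10; n_fr <- 300
  vals <- array(NA_real_, dim = c(n_lm, n_fr, 3))
  for (l in 1:n_lm) for (ch in 1:3)
    vals[l, , ch] <- sine_pulse(1.2, rate = 30, dur = 10) + rnorm(n_fr, 0, 0.05)
  vals[4, , ] <- 2   # flatlined landmark
  map <- st_map(vals, fps = 30, landmark_ids = 1:10,
                region_map = list(face = 1:10))
  out <- remove_low_variance(map)
  expect_equal(out$meta$dropped_ids, 4L)
  expect_equal(dim(out$values)[1], 9)
  # threshold zero keeps everything
  expect_equal(dim(remove_low_variance(map, threshold = 0)$values)[1], 10)
  # threshold above every variance errors
  expect_error(remove_low_variance(map, threshold = 1e6), "threshold")
})
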