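# Shared fixtures, built in code at test time.

# a sinusoidal pulse at `hz` sampled for `dur` seconds
sine_pulse <- function(hz, rate = 30, dur = 10, amp = 1, phase = 0) {
  t <- (seq_len(round(dur * rate)) - 1) / rate
  amp * sin(2 * pi * hz * t + phase)
}

# clean pulsatile RGB trace plus its (filtered, fps-rate) reference pulse
clean_pulsatile <- function(hr_bpm = 72, duration_s = 20, seed = 3,
                            noise_sd = 0, wander_amp = 0.02,
                            hrv_sd_bpm = 2) {
  cf <- synth_config(duration_s = duration_s, hr_bpm = hr_bpm,
                     hrv_sd_bpm = hrv_sd_bpm, noise_sd = noise_sd,
                     wander_amp = wander_amp, seed = seed)
  ppg <- simulate_ppg(cf)
  rgb <- simulate_rgb_trace(ppg, cf)
  ref <- bandpass_signal(detrend_signal(resample_to(ppg, cf$fps)))
  list(config = cf, ppg = ppg, rgb = rgb, ref = ref)
}

# toy identity task: target equals the second input channel, others noise
toy_pairs <- function(n, T = 300, rate = 30, seed = 0) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    tgt <- minmax_normalize(sin(2 * pi * 1.2 * (1:T) / rate +
                                  runif(1, 0, 2 * pi)))$samples
    X <- cbind(rnorm(T), tgt, rnorm(T), rnorm(T))
    colnames(X) <- c("ica", "lgi", "chrom", "pos")
    list(inputs = X, target = tgt, video = sprintf("v%03d", i),
         window = 1L, activity = "rest", fps = rate)
  }))
}

# brute-force DTW oracle: enumerate every monotone warping path
dtw_brute <- function(x, y) {
  n <- length(x); m <- length(y)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + (x[i] - y[j])^2
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  sqrt(best)
}

# cached heavyweight benchmark shared by the acceptance suite
benchmark_cache <- new.env(parent = emptyenv())
get_benchmark <- function(seed = 1) {
  key <- paste0("cv", seed)
  if (is.null(benchmark_cache[[key]]))
    benchmark_cache[[key]] <- run_synthetic_benchmark(seed = seed)
  benchmark_cache[[key]]
}
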