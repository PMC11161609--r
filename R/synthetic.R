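# Synthetic data: quasi-periodic PPG waveforms with systolic/diastolic
# morphology, noisy RGB observations of them, and (optionally) tiny frame
# sequences with landmark coordinates, so every downstream stage can be
# trained and tested offline.

#' Synthetic acquisition configuration
#'
#' Describes one simulated recording: heart rate and its beat-to-beat
#' jitter, beat morphology, observation noise, baseline wander and
#' illumination drift, per-channel pulsatile gains, frame rates and an
#' activity label. All randomness downstream flows from `seed`.
#'
#' @param duration_s Recording length in seconds.
#' @param fps Video frame rate (frames/second).
#' @param cppg_rate Contact-PPG sampling rate (samples/second), typically
#'   60 Hz as delivered by fingertip pulse oximeters.
#' @param hr_bpm Mean heart rate in beats/minute, in \[39, 240\].
#' @param hrv_sd_bpm SD of beat-to-beat heart-rate jitter (BPM).
#' @param diastolic_rel_amp Relative amplitude of the diastolic lobe in
#'   \[0, 1\].
#' @param diastolic_delay_frac Delay of the diastolic lobe after the
#'   systolic peak, as a fraction of the beat period, in (0, 1).
#' @param noise_sd SD of additive white observation noise (per channel,
#'   relative units).
#' @param wander_amp,wander_freq_hz Amplitude and frequency of the
#'   common-mode baseline wander (motion analogue).
#' @param illum_drift_amp Amplitude of the slow common-mode illumination
#'   drift.
#' @param pulsatile_gains Length-3 vector of per-channel (R, G, B)
#'   pulsatile amplitudes; the green gain is largest by default, as in
#'   real skin reflectance.
#' @param activity_label One of `"rest"`, `"talk"`, `"translation"`,
#'   `"rotation"`, `"gym"`.
#' @param seed Integer RNG seed.
#' @return An object of class `synth_config`.
#' @seealso [activity_preset()] for per-activity defaults.
#' @export
synth_config <- function(duration_s = 30, fps = 30, cppg_rate = 60,
                         hr_bpm = 70, hrv_sd_bpm = 2,
                         diastolic_rel_amp = 0.4, diastolic_delay_frac = 0.35,
                         noise_sd = 0.01, wander_amp = 0.02,
                         wander_freq_hz = 0.3, illum_drift_amp = 0.01,
                         pulsatile_gains = c(R = 0.003, G = 0.010, B = 0.006),
                         activity_label = "rest", seed = 1L) {
  check_num(duration_s, "duration_s", lower = 1)
  check_num(fps, "fps", lower = 1)
  check_num(cppg_rate, "cppg_rate", lower = 1)
  check_num(hr_bpm, "hr_bpm", lower = 39, upper = 240)
  if (fps <= 2 * (hr_bpm / 60))
    stop_cfg("fps", "must exceed twice the heart-rate fundamental (Nyquist)")
  check_num(hrv_sd_bpm, "hrv_sd_bpm", lower = 0)
  check_num(diastolic_rel_amp, "diastolic_rel_amp", lower = 0, upper = 1)
  check_num(diastolic_delay_frac, "diastolic_delay_frac",
            lower = 1e-6, upper = 1 - 1e-6)
  check_num(noise_sd, "noise_sd", lower = 0)
  check_num(wander_amp, "wander_amp", lower = 0)
  check_num(wander_freq_hz, "wander_freq_hz", lower = 0)
  check_num(illum_drift_amp, "illum_drift_amp", lower = 0)
  check_num(pulsatile_gains, "pulsatile_gains", lower = 0, len = 3L)
  if (!activity_label %in% c("rest", "talk", "translation", "rotation", "gym"))
    stop_cfg("activity_label", "must be one of rest/talk/translation/rotation/gym")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_cfg("seed", "must be a single integer")
  structure(
    list(duration_s = duration_s, fps = fps, cppg_rate = cppg_rate,
         hr_bpm = hr_bpm, hrv_sd_bpm = hrv_sd_bpm,
         diastolic_rel_amp = diastolic_rel_amp,
         diastolic_delay_frac = diastolic_delay_frac,
         noise_sd = noise_sd, wander_amp = wander_amp,
         wander_freq_hz = wander_freq_hz, illum_drift_amp = illum_drift_amp,
         pulsatile_gains = unname(pulsatile_gains),
         activity_label = activity_label, seed = as.integer(seed)),
    class = "synth_config")
}

#' Per-activity synthetic presets
#'
#' Preset noise regimes mirroring the difficulty ordering of common
#' recording conditions: rest is near-clean; talking adds mid-frequency
#' wander and noise; translation/rotation add strong wander and more
#' noise; gym combines high heart rate with the strongest noise. The
#' presets are analogues of those regimes, not calibrated replicas of any
#' particular video corpus.
#'
#' @param activity One of `"rest"`, `"talk"`, `"translation"`,
#'   `"rotation"`, `"gym"`.
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
activity_preset <- function(activity = c("rest", "talk", "translation",
                                         "rotation", "gym"), ...) {
  activity <- match.arg(activity)
  base <- switch(activity,
    rest        = list(hr_bpm = 65,  noise_sd = 0.002, wander_amp = 0.005,
                       wander_freq_hz = 0.25),
    talk        = list(hr_bpm = 75,  noise_sd = 0.003, wander_amp = 0.020,
                       wander_freq_hz = 0.90),
    translation = list(hr_bpm = 80,  noise_sd = 0.004, wander_amp = 0.030,
                       wander_freq_hz = 0.70),
    rotation    = list(hr_bpm = 85,  noise_sd = 0.004, wander_amp = 0.035,
                       wander_freq_hz = 0.80),
    gym         = list(hr_bpm = 120, noise_sd = 0.006, wander_amp = 0.040,
                       wander_freq_hz = 1.10))
  base$activity_label <- activity
  do.call(synth_config, modifyList(base, list(...)))
}

# Beat onset times covering [0, duration]; one heart-rate draw per beat.
beat_onsets <- function(config) {
  onsets <- 0
  hrs <- numeric(0)
  while (onsets[length(onsets)] < config$duration_s + 2) {
    hr <- rnorm(1, config$hr_bpm, config$hrv_sd_bpm)
    hr <- min(max(hr, 39), 240)
    hrs <- c(hrs, hr)
    onsets <- c(onsets, onsets[length(onsets)] + 60 / hr)
  }
  list(onsets = onsets[-length(onsets)], hr = hrs)
}

#' Simulate a contact-PPG waveform
#'
#' Generates a quasi-periodic pulse waveform at `cppg_rate`. Each beat is
#' the sum of two Gaussian lobes: a systolic lobe (SD 8% of the beat
#' period) and a delayed, smaller diastolic lobe, reproducing the two-peak
#' morphology of a real PPG. Beat-to-beat periods follow
#' `Normal(60/hr_bpm, jitter)` truncated to the physiologic band. The
#' waveform is scaled to unit peak amplitude.
#'
#' @param config A [synth_config()].
#' @return A [pulse_signal()] with label `"cppg"`; `meta` carries the
#'   config, the systolic peak times and the per-beat heart rates.
#' @export
simulate_ppg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    beats <- beat_onsets(config)
    n <- round(config$duration_s * config$cppg_rate)
    t <- (seq_len(n) - 1) / config$cppg_rate
    x <- numeric(n)
    sys_peaks <- numeric(0)
    for (i in seq_along(beats$onsets)) {
      period <- 60 / beats$hr[i]
      ts <- beats$onsets[i] + 0.2 * period      # systolic peak
      td <- ts + config$diastolic_delay_frac * period
      ss <- 0.08 * period
      sd_ <- 0.12 * period
      x <- x + exp(-(t - ts)^2 / (2 * ss^2)) +
        config$diastolic_rel_amp * exp(-(t - td)^2 / (2 * sd_^2))
      if (ts >= 0 && ts <= config$duration_s) sys_peaks <- c(sys_peaks, ts)
    }
    x <- x / max(x)
    pulse_signal(x, rate = config$cppg_rate, label = "cppg",
                 meta = list(config = config, systolic_peaks = sys_peaks,
                             beat_hr_bpm = beats$hr,
                             true_hr_bpm = mean(beats$hr)))
  })
}

#' Simulate an RGB observation of a PPG
#'
#' Observation model per channel `c`:
#' `baseline_c * (1 + drift(t) + wander(t) - gain_c * ppg(t) + eps_c(t))`.
#' Drift and wander are common-mode (shared by all channels, as a camera
#' sees illumination and motion), the white noise is per-channel, and the
#' pulsatile term is subtractive: more blood absorbs more light, so the
#' skin darkens at systole. The PPG is interpolated down to the video
#' frame rate.
#'
#' @param ppg A [pulse_signal()] whose rate is at least `config$fps`.
#' @param config The [synth_config()] used to generate `ppg`.
#' @param baselines Length-3 positive baseline reflectances (R, G, B).
#' @return An [rgb_trace()] at `config$fps`.
#' @export
simulate_rgb_trace <- function(ppg, config,
                               baselines = c(0.77, 0.57, 0.47)) {
  stopifnot(inherits(ppg, "pulse_signal"), inherits(config, "synth_config"))
  if (ppg$rate < config$fps)
    stop("'ppg' must be sampled at least as fast as the video frame rate")
  check_num(baselines, "baselines", lower = 1e-6, len = 3L)
  with_seed(config$seed + 1L, {
    n <- round(config$duration_s * config$fps)
    t <- (seq_len(n) - 1) / config$fps
    t_ppg <- (seq_along(ppg$samples) - 1) / ppg$rate
    p <- spline(t_ppg, ppg$samples, xout = t)$y
    ph_w <- runif(1, 0, 2 * pi)
    ph_d <- runif(1, 0, 2 * pi)
    wander <- config$wander_amp * sin(2 * pi * config$wander_freq_hz * t + ph_w)
    drift <- config$illum_drift_amp * sin(2 * pi * 0.05 * t + ph_d)
    vals <- vapply(1:3, function(ch) {
      eps <- rnorm(n, 0, config$noise_sd)
      baselines[ch] *
        (1 + drift + wander - config$pulsatile_gains[ch] * p + eps)
    }, numeric(n))
    rgb_trace(vals, fps = config$fps,
              meta = list(config = config, baselines = baselines))
  })
}

#' Simulate a frame sequence with landmark coordinates
#'
#' Renders each frame as a small uniform skin patch carrying that frame's
#' RGB value plus optional i.i.d. pixel noise, and emits 30 landmark
#' coordinates (10 forehead, 10 left cheek, 10 right cheek) positioned so
#' that every default-size patch stays inside the frame. Motion
#' activities (`translation`, `rotation`) translate the landmarks
#' sinusoidally within the constructed margin.
#'
#' @param rgb An [rgb_trace()].
#' @param config The generating [synth_config()].
#' @param size Frame side length in pixels.
#' @param pixel_noise_sd SD of i.i.d. pixel noise added per pixel/channel.
#' @param patch_px Patch side used to guarantee the in-bounds margin.
#' @return A list with `frames` (array `size x size x 3 x n_frames`),
#'   `coords` (array `n_frames x 30 x 2`, 0-based x = column, y = row),
#'   `landmark_ids`, and `region_map`.
#' @export
simulate_frames <- function(rgb, config, size = 64, pixel_noise_sd = 0,
                            patch_px = 30) {
  stopifnot(inherits(rgb, "rgb_trace"), inherits(config, "synth_config"))
  n <- nrow(rgb$values)
  lm <- default_landmarks()
  ids <- unlist(lm, use.names = FALSE)
  half <- floor(patch_px / 2)
  margin <- half + 4          # jitter amplitude < 4 keeps patches in-bounds
  lo <- margin
  hi <- size - 1 - margin
  if (hi <= lo) stop("'size' too small for the requested patch margin")
  # base positions: forehead along the top band, cheeks lower left/right
  grid10 <- function(x0, x1, y0, y1) {
    xs <- round(seq(x0, x1, length.out = 5))
    ys <- round(seq(y0, y1, length.out = 2))
    cbind(rep(xs, 2), rep(ys, each = 5))
  }
  span <- hi - lo
  base <- rbind(
    grid10(lo, hi, lo, lo + round(0.2 * span)),
    grid10(lo, lo + round(0.45 * span), hi - round(0.3 * span), hi),
    grid10(hi - round(0.45 * span), hi, hi - round(0.3 * span), hi))
  with_seed(config$seed + 2L, {
    t <- (seq_len(n) - 1) / rgb$fps
    moving <- config$activity_label %in% c("translation", "rotation")
    dx <- if (moving) round(3 * sin(2 * pi * 0.4 * t)) else rep(0L, n)
    dy <- if (moving) round(3 * cos(2 * pi * 0.4 * t)) else rep(0L, n)
    coords <- array(0, dim = c(n, length(ids), 2))
    for (f in seq_len(n)) {
      coords[f, , 1] <- base[, 1] + dx[f]
      coords[f, , 2] <- base[, 2] + dy[f]
    }
    frames <- array(0, dim = c(size, size, 3, n))
    for (f in seq_len(n)) {
      for (ch in 1:3) {
        plane <- matrix(rgb$values[f, ch], size, size)
        if (pixel_noise_sd > 0)
          plane <- plane + matrix(rnorm(size * size, 0, pixel_noise_sd),
                                  size, size)
        frames[, , ch, f] <- plane
      }
    }
    list(frames = frames, coords = coords, landmark_ids = ids,
         region_map = lm)
  })
}

#' Generate a collection of synthetic samples
#'
#' Runs [simulate_ppg()] and [simulate_rgb_trace()] for each configuration
#' and attaches per-sample provenance (video id, activity, seed).
#'
#' @param configs Non-empty list of [synth_config()] objects.
#' @return A list of samples (class `synth_dataset`); each sample holds
#'   `rgb`, `cppg`, `config`, `video_id`, `activity` and the generator's
#'   mean true heart rate.
#' @export
make_dataset <- function(configs) {
  if (!is.list(configs) || length(configs) == 0)
    stop("'configs' must be a non-empty list of synth_config objects")
  seeds <- vapply(configs, function(cf) cf$seed, integer(1))
  if (anyDuplicated(seeds))
    message("note: duplicate seeds in dataset configs")
  out <- lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    stopifnot(inherits(cf, "synth_config"))
    cppg <- simulate_ppg(cf)
    rgb <- simulate_rgb_trace(cppg, cf)
    list(rgb = rgb, cppg = cppg, config = cf,
         video_id = sprintf("video%03d", i),
         activity = cf$activity_label,
         true_hr_bpm = cppg$meta$true_hr_bpm)
  })
  structure(out, class = c("synth_dataset", "list"))
}

#' @export
print.synth_dataset <- function(x, ...) {
  acts <- table(vapply(x, `[[`, character(1), "activity"))
  cat(sprintf("<synth_dataset> %d videos (%s)\n", length(x),
              paste(names(acts), acts, sep = ":", collapse = ", ")))
  invisible(x)
}
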