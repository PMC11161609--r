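# Signal conditioning chain: linear detrend, zero-phase Butterworth
# bandpass, cubic resampling, low-variance landmark rejection, histogram
# equalization of spatiotemporal maps, fixed-length windowing and min-max
# normalization.

detrend_vec <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * x) / sum(tc^2)
  x - mean(x) - slope * tc
}

#' Remove a least-squares linear trend
#'
#' Fits and subtracts a straight line, leaving a zero-mean signal. A
#' constant input returns all zeros. Methods exist for [pulse_signal()]
#' (the samples), [rgb_trace()] (each channel) and plain numeric vectors.
#'
#' @param x Signal to detrend.
#' @param ... Unused.
#' @return Object of the same class as `x`.
#' @export
detrend_signal <- function(x, ...) UseMethod("detrend_signal")

#' @export
detrend_signal.numeric <- function(x, ...) {
  if (length(x) < 3) stop("detrend requires at least 3 samples")
  detrend_vec(x)
}

#' @export
detrend_signal.pulse_signal <- function(x, ...) {
  x$samples <- detrend_signal(x$samples)
  x
}

#' @export
detrend_signal.rgb_trace <- function(x, ...) {
  x$values <- apply(x$values, 2, detrend_vec)
  colnames(x$values) <- c("R", "G", "B")
  x
}

# Zero-phase Butterworth bandpass of a numeric vector. `order` follows
# the convention of the field's standard tooling: a "sixth-order"
# bandpass has 6 poles per band edge. Applied forward and backward so
# the net phase is zero; odd-reflection padding absorbs the filter
# transient at the signal edges.
bandpass_vec <- function(x, rate, low_hz, high_hz, order) {
  bf <- signal::butter(order, c(low_hz, high_hz) / (rate / 2),
                       type = "pass")
  n <- length(x)
  pad <- min(n - 1, ceiling(3 * rate / low_hz))
  front <- 2 * x[1] - x[(pad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth bandpass
#'
#' Sixth-order Butterworth bandpass with 0.65-4 Hz cutoffs by default
#' (the 39-240 BPM heart-rate band), applied forward-backward so
#' waveform morphology is preserved with zero phase distortion.
#'
#' @param x A [pulse_signal()], [rgb_trace()] or numeric vector.
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order per band edge.
#' @param rate Sampling rate; required only for numeric input.
#' @param ... Unused.
#' @return Object of the same class as `x`.
#' @export
bandpass_signal <- function(x, low_hz = 0.65, high_hz = 4, order = 6, ...) {
  UseMethod("bandpass_signal")
}

check_band <- function(rate, low_hz, high_hz, order) {
  if (order < 1) stop("'order' must be a positive integer")
  if (low_hz <= 0 || high_hz <= low_hz) stop("need 0 < low_hz < high_hz")
  if (rate <= 2 * high_hz)
    stop("sampling rate must exceed twice the upper band edge; resample first")
}

#' @export
bandpass_signal.numeric <- function(x, low_hz = 0.65, high_hz = 4, order = 6,
                                    rate, ...) {
  check_band(rate, low_hz, high_hz, order)
  bandpass_vec(x, rate, low_hz, high_hz, order)
}

#' @export
bandpass_signal.pulse_signal <- function(x, low_hz = 0.65, high_hz = 4,
                                         order = 6, ...) {
  check_band(x$rate, low_hz, high_hz, order)
  x$samples <- bandpass_vec(x$samples, x$rate, low_hz, high_hz, order)
  x
}

#' @export
bandpass_signal.rgb_trace <- function(x, low_hz = 0.65, high_hz = 4,
                                      order = 6, ...) {
  check_band(x$fps, low_hz, high_hz, order)
  x$values <- apply(x$values, 2, bandpass_vec, rate = x$fps,
                    low_hz = low_hz, high_hz = high_hz, order = order)
  colnames(x$values) <- c("R", "G", "B")
  x
}

#' Resample a pulse signal onto a uniform grid
#'
#' Cubic-spline interpolation onto a uniform grid at `target_rate`
#' spanning the same time interval, used to bring a 60 Hz contact-PPG
#' reference down to the video frame rate.
#'
#' @param x A [pulse_signal()].
#' @param target_rate New sampling rate in samples/second.
#' @return A [pulse_signal()] at `target_rate`.
#' @export
resample_to <- function(x, target_rate) {
  stopifnot(inherits(x, "pulse_signal"))
  check_num(target_rate, "target_rate", lower = .Machine$double.eps)
  n <- length(x$samples)
  span <- (n - 1) / x$rate
  if (span * target_rate < 1)
    stop("signal span too short to resample at the requested rate")
  t_old <- (seq_len(n) - 1) / x$rate
  n_new <- floor(span * target_rate) + 1
  t_new <- (seq_len(n_new) - 1) / target_rate
  y <- spline(t_old, x$samples, xout = t_new)$y
  pulse_signal(y, rate = target_rate, label = x$label, meta = x$meta)
}

#' Drop low-variance landmarks from a spatiotemporal map
#'
#' Computes the temporal variance of each landmark's series per channel
#' (after detrending and bandpassing, so slow drift does not mask a dead
#' landmark) and drops landmarks whose variance falls below the threshold
#' in any channel. The default threshold is relative: `1e-4` times the
#' median landmark variance of that channel, which is robust to the
#' overall signal scale; an absolute `threshold` overrides it.
#'
#' @param map An [st_map()].
#' @param threshold Absolute variance threshold, or `NULL` for the
#'   relative rule.
#' @return An [st_map()] with surviving landmarks; dropped ids are
#'   recorded in `meta$dropped_ids`.
#' @export
remove_low_variance <- function(map, threshold = NULL) {
  stopifnot(inherits(map, "st_map"))
  if (!is.null(threshold)) check_num(threshold, "threshold", lower = 0)
  n_lm <- dim(map$values)[1]
  v <- matrix(NA_real_, n_lm, 3)
  for (l in seq_len(n_lm)) {
    for (ch in 1:3) {
      s <- map$values[l, , ch]
      s <- detrend_vec(s)
      s <- bandpass_vec(s, map$fps, 0.65, min(4, map$fps / 2.5), 6)
      v[l, ch] <- var(s)
    }
  }
  keep <- if (is.null(threshold)) {
    thr <- 1e-4 * apply(v, 2, median)
    apply(v >= rep(thr, each = n_lm), 1, all)
  } else {
    apply(v >= threshold, 1, all)
  }
  if (!any(keep))
    stop("all landmarks fall below the variance threshold; review the threshold")
  out <- st_map(map$values[keep, , , drop = FALSE], fps = map$fps,
                landmark_ids = map$landmark_ids[keep],
                region_map = map$region_map, meta = map$meta)
  out$meta$dropped_ids <- map$landmark_ids[!keep]
  out
}

#' Histogram-equalize a spatiotemporal map
#'
#' Per channel, rank-transforms the values of the whole landmark x time
#' plane onto a uniform 256-level grid on \[0, 255\] (ties share their
#' average rank), a monotone transform that spreads the colour dynamic
#' range before region averaging.
#'
#' @param map An [st_map()].
#' @return An [st_map()] with equalized values.
#' @export
equalize_histogram <- function(map) {
  stopifnot(inherits(map, "st_map"))
  vals <- map$values
  for (ch in 1:3) {
    plane <- vals[, , ch]
    n <- length(plane)
    if (n > 1) {
      r <- rank(plane, ties.method = "average")
      vals[, , ch] <- round((r - 1) / (n - 1) * 255)
    } else {
      vals[, , ch] <- 127.5
    }
  }
  out <- map
  out$values <- vals
  out$meta$equalized <- TRUE
  out
}

#' Segment a signal into non-overlapping windows
#'
#' Cuts consecutive full windows of `window_s` seconds; a trailing
#' partial window is discarded (its sample count is recorded in the
#' `discarded_samples` attribute).
#'
#' @param x A [pulse_signal()].
#' @param window_s Window length in seconds (default 10).
#' @return List of [pulse_signal()] windows with `meta$window_index`.
#' @export
segment_windows <- function(x, window_s = 10) {
  stopifnot(inherits(x, "pulse_signal"))
  check_num(window_s, "window_s", lower = .Machine$double.eps)
  wlen <- round(window_s * x$rate)
  n <- length(x$samples)
  n_win <- floor(n / wlen)
  if (n_win < 1)
    stop(sprintf("signal (%d samples) shorter than one %g-s window (%d samples)",
                 n, window_s, wlen))
  wins <- lapply(seq_len(n_win), function(i) {
    s <- x$samples[((i - 1) * wlen + 1):(i * wlen)]
    m <- x$meta
    m$window_index <- i
    pulse_signal(s, rate = x$rate, label = x$label, meta = m)
  })
  attr(wins, "discarded_samples") <- n - n_win * wlen
  wins
}

#' Min-max normalize a window
#'
#' Rescales to span \[0, 1\]; a constant window maps to all 0.5 and is
#' flagged degenerate. The (min, max) state is retained so the transform
#' can be inverted.
#'
#' @param x A [pulse_signal()] or numeric vector.
#' @return List with `samples` (or a `pulse_signal` when the input was
#'   one), `min`, `max`, `degenerate`.
#' @export
minmax_normalize <- function(x) {
  s <- if (inherits(x, "pulse_signal")) x$samples else x
  if (length(s) == 0) stop("cannot normalize an empty window")
  lo <- min(s); hi <- max(s)
  degenerate <- (hi - lo) < .Machine$double.eps * max(1, abs(hi))
  y <- if (degenerate) rep(0.5, length(s)) else (s - lo) / (hi - lo)
  if (inherits(x, "pulse_signal")) {
    x$samples <- y
    list(signal = x, min = lo, max = hi, degenerate = degenerate)
  } else {
    list(samples = y, min = lo, max = hi, degenerate = degenerate)
  }
}
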