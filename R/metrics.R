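# Evaluation criteria: dynamic time warping, Pearson correlation, RMSE
# and Welch-based heart-rate error, computed per window and aggregated
# per video / activity / method.

as_samples <- function(x) if (inherits(x, "pulse_signal")) x$samples else x

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with squared-difference local cost;
#' the returned distance is the square root of the optimal warping
#' path's summed squared differences. No warping-window constraint is
#' applied (evaluation windows are short); the measure is symmetric and
#' zero iff the series are identical.
#'
#' @param x,y Numeric vectors or [pulse_signal()] objects (lengths may
#'   differ).
#' @return Non-negative scalar.
#' @export
dtw_distance <- function(x, y) {
  x <- as_samples(x); y <- as_samples(y)
  if (length(x) == 0 || length(y) == 0) stop("dtw: empty input")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y))))
    stop("dtw: inputs must be finite")
  dtw_distance_cpp(x, y)
}

#' Pearson correlation coefficient
#'
#' `sum((x-mx)(y-my)) / (sqrt(sum((x-mx)^2)) sqrt(sum((y-my)^2)))`.
#' A constant series makes the coefficient undefined; `NA` is returned
#' as the degeneracy marker (never 0).
#'
#' @param x,y Equal-length numeric vectors or [pulse_signal()] objects.
#' @return Scalar in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  x <- as_samples(x); y <- as_samples(y)
  if (length(x) != length(y)) stop("pearson_r: length mismatch")
  if (length(x) < 2) stop("pearson_r: need at least 2 samples")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx < .Machine$double.eps || syy < .Machine$double.eps) return(NA_real_)
  sum(xc * yc) / (sqrt(sxx) * sqrt(syy))
}

#' Root mean squared error
#'
#' `sqrt(sum((x - y)^2) / N)`.
#'
#' @param x,y Equal-length numeric vectors or [pulse_signal()] objects.
#' @return Non-negative scalar.
#' @export
rmse <- function(x, y) {
  x <- as_samples(x); y <- as_samples(y)
  if (length(x) != length(y)) stop("rmse: length mismatch")
  if (length(x) < 1) stop("rmse: empty input")
  sqrt(sum((x - y)^2) / length(x))
}

#' Welch power spectral density
#'
#' Averages modified periodograms of Hann-windowed, mean-removed,
#' 50%-overlapping segments (segment length 256 samples or the full
#' series if shorter), zero-padded to at least `nfft` bins.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in samples/second.
#' @param nperseg Segment length in samples.
#' @param overlap Fractional segment overlap.
#' @param nfft Minimum FFT length (zero-padding target).
#' @return List with `freq` (Hz, one-sided) and `power`.
#' @export
welch_psd <- function(x, rate, nperseg = 256, overlap = 0.5, nfft = 4096) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  if (nperseg < 8) stop("welch_psd: series too short")
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  nfft <- max(nfft, nperseg)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))
  scale <- rate * sum(w^2)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- fft(c(seg, numeric(nfft - nperseg)))
    p <- Mod(sp[1:(nfft %/% 2 + 1)])^2 / scale
    acc <- acc + p
  }
  list(freq = (0:(nfft %/% 2)) * rate / nfft, power = acc / length(starts))
}

#' Welch heart-rate estimate
#'
#' Estimates the heart rate as 60 times the frequency of the highest
#' Welch PSD peak, with the search restricted to the physiologic
#' 39-240 BPM band (0.65-4 Hz); peaks outside the band are never
#' returned. Ties resolve to the lowest frequency. If the in-band power
#' is entirely zero, `NA` is returned as the degeneracy marker.
#'
#' @param x A [pulse_signal()], or a numeric vector with `rate` given.
#' @param rate Sampling rate (ignored when `x` is a `pulse_signal`).
#' @param band_bpm Length-2 search band in BPM.
#' @param ... Passed to [welch_psd()].
#' @return Heart rate in BPM, or `NA`.
#' @export
estimate_hr_welch <- function(x, rate = NULL, band_bpm = c(39, 240), ...) {
  if (inherits(x, "pulse_signal")) {
    rate <- x$rate
    x <- x$samples
  }
  if (is.null(rate)) stop("estimate_hr_welch: 'rate' required for numeric input")
  psd <- welch_psd(x, rate, ...)
  sel <- psd$freq >= band_bpm[1] / 60 & psd$freq <= band_bpm[2] / 60
  if (!any(sel) || max(psd$power[sel]) <= 0) return(NA_real_)
  f <- psd$freq[sel]
  p <- psd$power[sel]
  60 * f[which.max(p)]
}

#' Absolute heart-rate difference
#'
#' `|HR(rppg) - HR(cppg)|` with both heart rates estimated by
#' [estimate_hr_welch()]. A degenerate estimate on either side
#' propagates as `NA`.
#'
#' @param rppg,cppg [pulse_signal()] objects (or numeric with `rate`).
#' @param rate Sampling rate for numeric inputs.
#' @return Non-negative BPM difference, or `NA`.
#' @export
delta_hr <- function(rppg, cppg, rate = NULL) {
  h1 <- estimate_hr_welch(rppg, rate = rate)
  h2 <- estimate_hr_welch(cppg, rate = rate)
  abs(h1 - h2)
}

#' Evaluate rPPG windows against their contact-PPG targets
#'
#' Computes all four criteria (DTW, Pearson r, RMSE, |dHR|) for every
#' (window, method) pair and aggregates arithmetic means with 95%
#' confidence intervals per method, per (video, method) and per
#' (activity, method). Degenerate windows (constant signals) yield `NA`
#' rows that are excluded from aggregates, with the exclusion count
#' reported.
#'
#' @param pairs List of entries, each a list with elements `pred`
#'   (numeric or [pulse_signal()]), `target` (same length), `method`,
#'   `video`, `window`, `activity`, and `rate` (needed when `pred` is
#'   numeric).
#' @return Object of class `metric_report`: list with `rows`
#'   (data.frame), `per_method`, `per_video`, `per_activity` aggregate
#'   data.frames, `n_windows` and `n_degenerate`.
#' @export
evaluate_windows <- function(pairs) {
  if (length(pairs) == 0) stop("evaluate_windows: no pairs supplied")
  rows <- lapply(pairs, function(p) {
    rate <- if (inherits(p$pred, "pulse_signal")) p$pred$rate else p$rate
    pred <- as_samples(p$pred)
    targ <- as_samples(p$target)
    hr_r <- estimate_hr_welch(pred, rate = rate)
    hr_c <- estimate_hr_welch(targ, rate = rate)
    data.frame(
      video = p$video %||% NA_character_,
      window = p$window %||% NA_integer_,
      activity = p$activity %||% NA_character_,
      method = p$method,
      dtw = dtw_distance(pred, targ),
      r = pearson_r(pred, targ),
      rmse = rmse(pred, targ),
      hr_rppg_bpm = hr_r,
      hr_cppg_bpm = hr_c,
      delta_hr_bpm = abs(hr_r - hr_c),
      stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  metrics <- c("dtw", "r", "rmse", "delta_hr_bpm")
  degenerate <- !stats::complete.cases(rows[, metrics])
  agg <- function(by) {
    keys <- unique(rows[, by, drop = FALSE])
    out <- lapply(seq_len(nrow(keys)), function(i) {
      sel <- rep(TRUE, nrow(rows))
      for (b in by) sel <- sel & rows[[b]] == keys[[b]][i]
      sub <- rows[sel & !degenerate, , drop = FALSE]
      res <- keys[i, , drop = FALSE]
      for (m in metrics) {
        ci <- mean_ci(sub[[m]])
        res[[paste0(m, "_mean")]] <- ci[["mean"]]
        res[[paste0(m, "_lo")]] <- ci[["lo"]]
        res[[paste0(m, "_hi")]] <- ci[["hi"]]
      }
      res$n <- nrow(sub)
      res
    })
    do.call(rbind, out)
  }
  structure(
    list(rows = rows,
         per_method = agg("method"),
         per_video = agg(c("video", "method")),
         per_activity = agg(c("activity", "method")),
         n_windows = nrow(rows),
         n_degenerate = sum(degenerate)),
    class = "metric_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d (window x method) rows, %d degenerate\n",
              x$n_windows, x$n_degenerate))
  print(x$per_method, digits = 3)
  invisible(x)
}
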