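# Classical per-trace rPPG extractors: GREEN, CHROM, POS, LGI, ICA.
# Each maps an RGB trace to a single candidate pulse signal, oriented so
# systolic peaks point upward (non-negative correlation with the negated
# green channel).

orient_to_green <- function(s, trace) {
  g <- trace$values[, "G"]
  ref <- -(g - mean(g))
  if (sd(s) < .Machine$double.eps || sd(ref) < .Machine$double.eps) return(s)
  if (cor(s, ref) < 0) -s else s
}

check_trace <- function(trace) {
  stopifnot(inherits(trace, "rgb_trace"))
  invisible(trace)
}

#' GREEN baseline extractor
#'
#' The negated, mean-removed green channel: the simplest rPPG estimate,
#' relying on the green channel carrying the strongest pulsatile
#' component. Negation makes systole point upward (blood absorbs light,
#' so raw intensity dips at systole).
#'
#' @param trace An [rgb_trace()].
#' @return A [pulse_signal()] with label `"green"`.
#' @export
extract_green <- function(trace) {
  check_trace(trace)
  g <- trace$values[, "G"]
  pulse_signal(-(g - mean(g)), rate = trace$fps, label = "green",
               meta = trace$meta)
}

#' CHROM chrominance extractor
#'
#' Projects temporally mean-normalized channels onto fixed chrominance
#' axes: `Xs = 3 Rn - 2 Gn`, `Ys = 1.5 Rn + Gn - 1.5 Bn`, then
#' `S = Xs - (sd(Xs)/sd(Ys)) Ys`, which cancels identical relative
#' intensity modulation across channels by construction. If `sd(Ys)` is
#' zero the projection degenerates to `Xs`.
#'
#' @param trace An [rgb_trace()] with strictly positive channel means.
#' @return A mean-removed [pulse_signal()] with label `"chrom"`.
#' @export
extract_chrom <- function(trace) {
  check_trace(trace)
  mu <- colMeans(trace$values)
  if (any(mu <= 0))
    stop("chrom: channel means must be positive (non-physical trace)")
  Rn <- trace$values[, "R"] / mu[1]
  Gn <- trace$values[, "G"] / mu[2]
  Bn <- trace$values[, "B"] / mu[3]
  Xs <- 3 * Rn - 2 * Gn
  Ys <- 1.5 * Rn + Gn - 1.5 * Bn
  s_y <- sd(Ys)
  s <- if (s_y < .Machine$double.eps) Xs else Xs - (sd(Xs) / s_y) * Ys
  s <- s - mean(s)
  pulse_signal2(orient_to_green(s, trace), trace, "chrom")
}

# pulse_signal allowing an all-zero vector (extractors can legitimately
# return exact zeros, e.g. on pure intensity modulation)
pulse_signal2 <- function(s, trace, label) {
  structure(list(samples = as.numeric(s), rate = trace$fps, label = label,
                 meta = trace$meta),
            class = "pulse_signal")
}

#' POS (plane-orthogonal-to-skin) extractor
#'
#' Sliding-window projection (window 1.6 s, slide 1 frame) of
#' mean-normalized channels onto the plane orthogonal to the skin-tone
#' intensity axis: within each segment `S1 = Gn - Bn`,
#' `S2 = -2 Rn + Gn + Bn`, `h = S1 + (sd(S1)/sd(S2)) S2`; the
#' mean-removed `h` values are overlap-added into the output. A segment
#' with `sd(S2) = 0` contributes `S1` alone.
#'
#' @param trace An [rgb_trace()] with positive channel means in every
#'   sliding segment.
#' @param window_s Sliding window length in seconds (default 1.6).
#' @return A [pulse_signal()] with label `"pos"`.
#' @export
extract_pos <- function(trace, window_s = 1.6) {
  check_trace(trace)
  n <- nrow(trace$values)
  w <- round(window_s * trace$fps)
  if (w < 2) stop("pos: sliding segment shorter than 2 samples")
  w <- min(w, n)
  h <- numeric(n)
  for (start in seq_len(n - w + 1)) {
    seg <- trace$values[start:(start + w - 1), , drop = FALSE]
    mu <- colMeans(seg)
    if (any(mu <= 0))
      stop("pos: channel means must be positive in every sliding segment")
    Rn <- seg[, 1] / mu[1]; Gn <- seg[, 2] / mu[2]; Bn <- seg[, 3] / mu[3]
    S1 <- Gn - Bn
    S2 <- -2 * Rn + Gn + Bn
    s2 <- sd(S2)
    hi <- if (s2 < .Machine$double.eps) S1 else S1 + (sd(S1) / s2) * S2
    hi <- hi - mean(hi)
    h[start:(start + w - 1)] <- h[start:(start + w - 1)] + hi
  }
  h <- h - mean(h)
  pulse_signal2(orient_to_green(h, trace), trace, "pos")
}

#' LGI (local group invariance) extractor
#'
#' Computes the SVD of the mean-removed 3 x T channel matrix and projects
#' the data onto the subspace orthogonal to the leading singular vector
#' (`I - u1 u1'`), removing the dominant global colour/intensity
#' direction. The projected data decomposes along the remaining singular
#' directions; the component with maximal in-band (0.65-4 Hz) spectral
#' power is returned, scaled by the leading singular value so the output
#' is invariant to a global gain and to rotations of colour space.
#'
#' @param trace An [rgb_trace()].
#' @return A [pulse_signal()] with label `"lgi"`.
#' @export
extract_lgi <- function(trace) {
  check_trace(trace)
  C <- t(trace$values)              # 3 x T
  C <- C - rowMeans(C)
  sv <- svd(C)
  if (sv$d[1] < .Machine$double.eps) stop("lgi: input has rank 0")
  # component i of the projected data (I - u1 u1') C is d_i * v_i(t)
  Y <- t(sv$v[, 2:3, drop = FALSE]) * (sv$d[2:3] / sv$d[1])
  pw <- apply(Y, 1, function(row) in_band_peak_power(row, trace$fps))
  s <- Y[which.max(pw), ]
  s <- s - mean(s)
  pulse_signal2(orient_to_green(s, trace), trace, "lgi")
}

# peak Welch PSD value inside the heart-rate band (0 for degenerate rows)
in_band_peak_power <- function(x, rate, low_hz = 0.65, high_hz = 4) {
  if (sd(x) < .Machine$double.eps) return(0)
  psd <- welch_psd(x, rate)
  sel <- psd$freq >= low_hz & psd$freq <= high_hz
  if (!any(sel)) return(0)
  max(psd$power[sel])
}

# ICA by joint approximate diagonalization of fourth-order cumulant
# matrices (JADE) on whitened data: deterministic Jacobi rotations, the
# standard ICA engine for short multi-channel physiological traces.
# Whitening keeps only directions with non-negligible eigenvalues, so
# rank-deficient inputs (e.g. noiseless traces, collinear after
# filtering) reduce to their actual dimension instead of failing.
ica_core <- function(X, max_sweeps = 100) {
  Xc <- X - rowMeans(X)
  Tn <- ncol(Xc)
  Cv <- tcrossprod(Xc) / Tn
  eg <- eigen(Cv, symmetric = TRUE)
  keep <- eg$values > 1e-12 * max(eg$values)
  k <- sum(keep)
  E <- eg$vectors[, keep, drop = FALSE]
  D <- eg$values[keep]
  Z <- diag(1 / sqrt(D), k) %*% t(E) %*% Xc    # k x T, whitened
  if (k == 1) return(list(S = Z, iterations = 0L, k = 1L))

  # parallel set of cumulant matrices
  R <- diag(k)
  CM <- matrix(0, k, 0)
  for (im in seq_len(k)) {
    Xim <- Z[im, ]
    Q <- (sweep(Z, 2, Xim * Xim, `*`) %*% t(Z)) / Tn - R -
      2 * tcrossprod(R[, im])
    CM <- cbind(CM, Q)
    if (im > 1) {
      for (jm in seq_len(im - 1)) {
        Xjm <- Z[jm, ]
        Q <- sqrt(2) * ((sweep(Z, 2, Xim * Xjm, `*`) %*% t(Z)) / Tn -
                          tcrossprod(R[, im], R[, jm]) -
                          tcrossprod(R[, jm], R[, im]))
        CM <- cbind(CM, Q)
      }
    }
  }
  nbcm <- ncol(CM) / k
  V <- diag(k)
  thresh <- 1e-6 / sqrt(Tn)
  sweep_n <- 0L
  repeat {
    sweep_n <- sweep_n + 1L
    rotated <- FALSE
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) {
        Ip <- seq(p, k * nbcm, by = k)
        Iq <- seq(q, k * nbcm, by = k)
        g <- rbind(CM[p, Ip] - CM[q, Iq], CM[p, Iq] + CM[q, Ip])
        gg <- tcrossprod(g)
        ton <- gg[1, 1] - gg[2, 2]
        toff <- gg[1, 2] + gg[2, 1]
        theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
        if (abs(theta) > thresh) {
          rotated <- TRUE
          cs <- cos(theta); sn <- sin(theta)
          G <- matrix(c(cs, sn, -sn, cs), 2, 2)
          V[, c(p, q)] <- V[, c(p, q)] %*% G
          CM[c(p, q), ] <- t(G) %*% CM[c(p, q), ]
          tmp <- cs * CM[, Ip] + sn * CM[, Iq]
          CM[, Iq] <- -sn * CM[, Ip] + cs * CM[, Iq]
          CM[, Ip] <- tmp
        }
      }
    }
    if (!rotated) break
    if (sweep_n >= max_sweeps)
      stop(sprintf("ica: no convergence after %d Jacobi sweeps", sweep_n))
  }
  list(S = t(V) %*% Z, iterations = sweep_n, k = k)
}

#' ICA extractor
#'
#' Independent component analysis of the whitened channels by joint
#' approximate diagonalization of fourth-order cumulant matrices (JADE);
#' returns the component whose Welch power spectral density peaks
#' highest inside the 0.65-4 Hz heart-rate band (ties broken by lowest
#' component index), sign-oriented so its correlation with the negated
#' green channel is non-negative. The decomposition is deterministic
#' algebra, so identical inputs (and any `seed`) give identical output.
#' When the pulsatile band carries almost no power the result is flagged
#' low-confidence in `meta$low_confidence`.
#'
#' @param trace An [rgb_trace()] with length >= 30.
#' @param seed Accepted for interface stability with seeded extractors;
#'   the decomposition itself is deterministic.
#' @return A [pulse_signal()] with label `"ica"`.
#' @export
extract_ica <- function(trace, seed = 1L) {
  check_trace(trace)
  n <- nrow(trace$values)
  if (n < 30) stop("ica: need at least 30 frames")
  res <- ica_core(t(trace$values))
  S <- res$S
  pw <- apply(S, 1, function(row) in_band_peak_power(row, trace$fps))
  tot <- apply(S, 1, function(row) {
    psd <- welch_psd(row, trace$fps)
    sum(psd$power)
  })
  best <- which.max(pw)             # which.max takes the lowest index on ties
  s <- S[best, ]
  s <- s - mean(s)
  out <- pulse_signal2(orient_to_green(s, trace), trace, "ica")
  out$meta$ica_iterations <- res$iterations
  out$meta$low_confidence <- pw[best] < 0.5 * sum(tot) / length(s)
  out
}

#' Extractor registry
#'
#' Named registry of the available extractors, keyed by method name.
#' Extension hook: additional methods can be run by passing your own
#' functions of the same signature to [extract_all()].
#'
#' @return Named list of extractor functions.
#' @export
rppg_extractors <- function() {
  list(green = extract_green,
       chrom = extract_chrom,
       pos = extract_pos,
       lgi = extract_lgi,
       ica = extract_ica)
}

#' Run all model-input extractors on a trace
#'
#' Runs the four fusion-model input methods in the fixed channel order
#' (ica, lgi, chrom, pos) and stacks their outputs column-wise.
#'
#' @param trace An [rgb_trace()].
#' @param methods Character vector of method names (registry keys), in
#'   output channel order.
#' @param seed Seed forwarded to seeded extractors (ICA).
#' @return Numeric matrix `n_frames x length(methods)` with method names
#'   as column names.
#' @export
extract_all <- function(trace, methods = c("ica", "lgi", "chrom", "pos"),
                        seed = 1L) {
  check_trace(trace)
  reg <- rppg_extractors()
  unknown <- setdiff(methods, names(reg))
  if (length(unknown) > 0)
    stop(sprintf("unknown extractor(s): %s", paste(unknown, collapse = ", ")))
  cols <- lapply(methods, function(m) {
    fn <- reg[[m]]
    out <- tryCatch(
      if (m == "ica") fn(trace, seed = seed) else fn(trace),
      error = function(e) stop(sprintf("extractor '%s' failed: %s",
                                       m, conditionMessage(e)), call. = FALSE))
    out$samples
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- methods
  mat
}
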