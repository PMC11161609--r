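# Core data containers: 1-D pulse signals, 3-channel colour traces and
# landmark x time x channel spatiotemporal maps. Lightweight S3, validated
# at construction.

#' Pulse signal
#'
#' A single 1-D pulse waveform with its sampling rate and a provenance
#' label: the output of one extractor, the fused model output, or a
#' contact PPG reference.
#'
#' @param samples Numeric vector of unitless amplitudes (length >= 2).
#' @param rate Sampling rate in samples/second.
#' @param label Provenance tag, e.g. `"green"`, `"chrom"`, `"pos"`,
#'   `"lgi"`, `"ica"`, `"fused"`, `"cppg"`.
#' @param meta Optional named list of provenance metadata
#'   (video id, window index, activity, ...).
#' @return An object of class `pulse_signal`.
#' @export
pulse_signal <- function(samples, rate, label = "unknown", meta = list()) {
  if (!is.numeric(samples) || length(samples) < 2)
    stop("'samples' must be a numeric vector of length >= 2")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("'samples' must be finite")
  check_num(rate, "rate", lower = .Machine$double.eps)
  structure(
    list(samples = as.numeric(samples), rate = as.numeric(rate),
         label = as.character(label), meta = meta),
    class = "pulse_signal")
}

#' @export
print.pulse_signal <- function(x, ...) {
  cat(sprintf("<pulse_signal> label=%s  n=%d  rate=%g Hz  duration=%.2f s\n",
              x$label, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.pulse_signal <- function(x) length(x$samples)

#' RGB colour trace
#'
#' A time-indexed 3-channel colour series at a stated frame rate: the mean
#' skin colour of a region (or the whole face) per video frame.
#'
#' @param values Numeric matrix with one row per frame and columns
#'   `R`, `G`, `B` (in that fixed order).
#' @param fps Frame rate in frames/second.
#' @param meta Optional named list of metadata.
#' @return An object of class `rgb_trace`.
#' @export
rgb_trace <- function(values, fps, meta = list()) {
  values <- as.matrix(values)
  if (ncol(values) != 3) stop("'values' must have exactly 3 columns (R, G, B)")
  if (nrow(values) < 2) stop("'values' must have at least 2 frames")
  if (anyNA(values) || any(!is.finite(values))) stop("'values' must be finite")
  check_num(fps, "fps", lower = .Machine$double.eps)
  colnames(values) <- c("R", "G", "B")
  structure(list(values = values, fps = as.numeric(fps), meta = meta),
            class = "rgb_trace")
}

#' @export
print.rgb_trace <- function(x, ...) {
  cat(sprintf("<rgb_trace> frames=%d  fps=%g  duration=%.2f s\n",
              nrow(x$values), x$fps, nrow(x$values) / x$fps))
  invisible(x)
}

#' Spatiotemporal map
#'
#' Patch-mean colours organised as a landmarks x frames x channels array,
#' the intermediate between video frames and 1-D colour traces.
#'
#' @param values Numeric array of dimension
#'   `n_landmarks x n_frames x 3` (channels in R, G, B order).
#' @param fps Frame rate in frames/second.
#' @param landmark_ids Integer vector of landmark ids (one per row).
#' @param region_map Named list mapping region name to the landmark ids it
#'   contains (see [default_landmarks()]).
#' @param meta Optional named list of metadata.
#' @return An object of class `st_map`.
#' @export
st_map <- function(values, fps, landmark_ids, region_map, meta = list()) {
  if (!is.array(values) || length(dim(values)) != 3 || dim(values)[3] != 3)
    stop("'values' must be a landmarks x frames x 3 array")
  if (anyNA(values) || any(!is.finite(values))) stop("'values' must be finite")
  if (length(landmark_ids) != dim(values)[1])
    stop("'landmark_ids' must have one entry per landmark row")
  check_num(fps, "fps", lower = .Machine$double.eps)
  structure(
    list(values = values, fps = as.numeric(fps),
         landmark_ids = as.integer(landmark_ids),
         region_map = region_map, meta = meta),
    class = "st_map")
}

#' @export
print.st_map <- function(x, ...) {
  cat(sprintf("<st_map> landmarks=%d  frames=%d  fps=%g  regions=%s\n",
              dim(x$values)[1], dim(x$values)[2], x$fps,
              paste(names(x$region_map), collapse = ",")))
  invisible(x)
}
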