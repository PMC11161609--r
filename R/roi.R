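# Region-of-interest stage: turn frames plus landmark pixel coordinates
# into per-landmark patch-mean colour series (a spatiotemporal map), then
# reduce the map to region and whole-face RGB traces.

#' Default facial landmark layout
#'
#' The 30-landmark layout used for skin colour sampling: 10 landmarks per
#' region on the forehead, left cheek and right cheek, identified by the
#' face-mesh ids commonly used for those regions. Landmark detection
#' itself is delegated to an external detector behind this interface;
#' callers supply per-frame coordinates for these ids.
#'
#' @return Named list with elements `forehead`, `left_cheek`,
#'   `right_cheek`, each an integer vector of 10 landmark ids.
#' @export
default_landmarks <- function() {
  list(
    forehead    = c(107L, 66L, 69L, 109L, 10L, 338L, 299L, 296L, 336L, 9L),
    left_cheek  = c(118L, 119L, 100L, 126L, 209L, 49L, 129L, 203L, 205L, 50L),
    right_cheek = c(347L, 348L, 329L, 355L, 429L, 279L, 358L, 423L, 425L, 280L))
}

#' Extract per-landmark patch means
#'
#' For every frame and landmark, averages the `patch_px x patch_px` pixel
#' window centred on the landmark coordinate, independently per colour
#' channel. Patches are clipped at frame borders and the mean is taken
#' over the surviving pixels. Coordinates are 0-based (x = column,
#' y = row) and are rounded to the nearest integer pixel.
#'
#' @param frames Array `height x width x 3 x n_frames` of pixel values.
#' @param coords Array `n_frames x n_landmarks x 2` of 0-based (x, y)
#'   pixel coordinates.
#' @param fps Frame rate in frames/second.
#' @param landmark_ids Integer ids, one per landmark column of `coords`.
#' @param region_map Region-to-ids mapping; defaults to
#'   [default_landmarks()].
#' @param patch_px Patch side length in pixels (default 30).
#' @return An [st_map()].
#' @export
extract_patch_means <- function(frames, coords, fps,
                                landmark_ids = unlist(default_landmarks(),
                                                      use.names = FALSE),
                                region_map = default_landmarks(),
                                patch_px = 30) {
  if (!is.array(frames) || length(dim(frames)) != 4 || dim(frames)[3] != 3)
    stop("'frames' must be a height x width x 3 x n_frames array")
  d <- dim(frames)
  h <- d[1]; w <- d[2]; n_frames <- d[4]
  if (!is.array(coords) || length(dim(coords)) != 3 ||
      dim(coords)[1] != n_frames || dim(coords)[3] != 2)
    stop("'coords' must be an n_frames x n_landmarks x 2 array")
  n_lm <- dim(coords)[2]
  if (length(landmark_ids) != n_lm)
    stop("'landmark_ids' must have one id per landmark")
  half <- floor(patch_px / 2)
  vals <- array(NA_real_, dim = c(n_lm, n_frames, 3))
  for (f in seq_len(n_frames)) {
    for (l in seq_len(n_lm)) {
      cx <- round(coords[f, l, 1])  # 0-based column
      cy <- round(coords[f, l, 2])  # 0-based row
      x0 <- max(cx - half, 0); x1 <- min(cx - half + patch_px - 1, w - 1)
      y0 <- max(cy - half, 0); y1 <- min(cy - half + patch_px - 1, h - 1)
      if (x1 < x0 || y1 < y0)
        stop(sprintf("landmark %d entirely outside frame %d",
                     landmark_ids[l], f))
      for (ch in 1:3)
        vals[l, f, ch] <- mean(frames[(y0 + 1):(y1 + 1),
                                      (x0 + 1):(x1 + 1), ch, f])
    }
  }
  st_map(vals, fps = fps, landmark_ids = landmark_ids,
         region_map = region_map, meta = list(patch_px = patch_px))
}

#' Average a region of a spatiotemporal map
#'
#' Unweighted mean over the region's landmarks, per frame and channel.
#'
#' @param map An [st_map()].
#' @param region Region name present in `map$region_map`.
#' @return An [rgb_trace()].
#' @export
region_average <- function(map, region) {
  stopifnot(inherits(map, "st_map"))
  if (!region %in% names(map$region_map))
    stop(sprintf("unknown region '%s'", region))
  rows <- which(map$landmark_ids %in% map$region_map[[region]])
  if (length(rows) == 0)
    stop(sprintf("region '%s' has no surviving landmarks", region))
  vals <- apply(map$values[rows, , , drop = FALSE], c(2, 3), mean)
  rgb_trace(vals, fps = map$fps,
            meta = list(region = region, n_landmarks = length(rows)))
}

#' Combine region traces into a whole-face trace
#'
#' Unweighted mean of the region traces, per frame and channel.
#'
#' @param traces List of [rgb_trace()] objects of equal length and fps.
#' @return An [rgb_trace()].
#' @export
combine_regions <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1)
  lens <- vapply(traces, function(tr) nrow(tr$values), integer(1))
  fps <- vapply(traces, function(tr) tr$fps, numeric(1))
  if (length(unique(lens)) != 1) stop("region traces have mismatched lengths")
  if (length(unique(fps)) != 1) stop("region traces have mismatched fps")
  vals <- Reduce(`+`, lapply(traces, `[[`, "values")) / length(traces)
  rgb_trace(vals, fps = fps[1],
            meta = list(combined_from = length(traces)))
}

#' Full map-to-trace reduction
#'
#' Applies [region_average()] to each region then [combine_regions()],
#' the standard reduction from a spatiotemporal map to the whole-face
#' RGB trace fed to the extractors.
#'
#' @param map An [st_map()].
#' @return An [rgb_trace()].
#' @export
map_to_trace <- function(map) {
  combine_regions(lapply(names(map$region_map),
                         function(r) region_average(map, r)))
}
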