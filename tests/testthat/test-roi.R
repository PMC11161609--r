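# Patch means, region averaging and whole-face combination.

make_frames <- function(n_frames, size = 40, fill = c(10, 20, 30)) {
  fr <- array(0, dim = c(size, size, 3, n_frames))
  for (ch in 1:3) fr[, , ch, ] <- fill[ch]
  fr
}

const_coords <- function(n_frames, xy) {
  coords <- array(0, dim = c(n_frames, nrow(xy), 2))
  for (f in seq_len(n_frames)) coords[f, , ] <- xy
  coords
}

test_that("uniform frames give the fill value at every landmark", {
  fr <- make_frames(3)
  xy <- cbind(c(15, 20, 25), c(15, 20, 25))
  map <- extract_patch_means(fr, const_coords(3, xy), fps = 30,
                             landmark_ids = 1:3,
                             region_map = list(all = 1:3), patch_px = 10)
  expect_true(all(map$values[, , 1] == 10))
  expect_true(all(map$values[, , 2] == 20))
  expect_true(all(map$values[, , 3] == 30))
})

test_that("a corner landmark averages only the clipped intersection", {
  size <- 40
  fr <- array(0, dim = c(size, size, 3, 1))
  for (ch in 1:3) fr[, , ch, 1] <- matrix(seq_len(size * size), size, size)
  xy <- matrix(c(0, 0), 1, 2)
  map <- extract_patch_means(fr, const_coords(1, xy), fps = 30,
                             landmark_ids = 1L, region_map = list(all = 1L),
                             patch_px = 30)
  # patch centred at (0,0) with half = 15 clips to rows/cols 1..15
  oracle <- mean(fr[1:15, 1:15, 1, 1])
  expect_equal(map$values[1, 1, 1], oracle)
  # fully outside errors with the landmark id
  expect_error(
    extract_patch_means(fr, const_coords(1, matrix(c(200, 200), 1, 2)),
                        fps = 30, landmark_ids = 99L,
                        region_map = list(all = 99L), patch_px = 10),
    "99")
})

test_that("patch means scale linearly with pixel values", {
  fr <- array(runif(20 * 20 * 3 * 2), dim = c(20, 20, 3, 2))
  xy <- matrix(c(10, 10), 1, 2)
  m1 <- extract_patch_means(fr, const_coords(2, xy), fps = 30,
                            landmark_ids = 1L, region_map = list(all = 1L),
                            patch_px = 8)
  m2 <- extract_patch_means(fr * 3.5, const_coords(2, xy), fps = 30,
                            landmark_ids = 1L, region_map = list(all = 1L),
                            patch_px = 8)
  expect_equal(m2$values, m1$values * 3.5)
})

test_that("region averaging is the unweighted landmark mean", {
  n_lm <- 10; n_fr <- 5
  vals <- array(0, dim = c(n_lm, n_fr, 3))
  x <- matrix(runif(n_fr * 3), n_fr, 3)
  for (ch in 1:3) vals[1, , ch] <- x[, ch]   # one landmark = x, nine = 0
  map <- st_map(vals, fps = 30, landmark_ids = 1:10,
                region_map = list(face = 1:10))
  tr <- region_average(map, "face")
  expect_equal(tr$values, x / 10, ignore_attr = TRUE)
  # identical landmarks reproduce any landmark's trace
  for (l in 1:10) for (ch in 1:3) vals[l, , ch] <- x[, ch]
  map2 <- st_map(vals, fps = 30, landmark_ids = 1:10,
                 region_map = list(face = 1:10))
  expect_equal(region_average(map2, "face")$values, x, ignore_attr = TRUE)
  # permuting landmarks leaves the average unchanged
  perm <- c(4, 1, 3, 2, 10, 6, 5, 9, 7, 8)
  map3 <- st_map(vals[perm, , , drop = FALSE], fps = 30,
                 landmark_ids = (1:10)[perm],
                 region_map = list(face = 1:10))
  expect_equal(region_average(map3, "face")$values,
               region_average(map2, "face")$values)
  expect_error(region_average(map2, "nose"), "unknown region")
})

test_that("combining regions averages per frame and channel", {
  mk <- function(vals) rgb_trace(vals, fps = 30)
  a <- mk(matrix(c(3, 3, 0, 0, 0, 0), 2, 3))
  b <- mk(matrix(c(0, 0, 3, 3, 0, 0), 2, 3))
  c3 <- mk(matrix(c(0, 0, 0, 0, 3, 3), 2, 3))
  comb <- combine_regions(list(a, b, c3))
  expect_true(all(comb$values == 1))
  expect_equal(combine_regions(list(a, a, a))$values, a$values)
  expect_equal(combine_regions(list(c3, a, b))$values, comb$values)
  bad <- mk(matrix(1, 3, 3))
  expect_error(combine_regions(list(a, bad)), "length")
})

test_that("default landmark layout has 30 ids, 10 per region", {
  lm <- default_landmarks()
  expect_named(lm, c("forehead", "left_cheek", "right_cheek"))
  expect_true(all(lengths(lm) == 10))
  expect_equal(length(unique(unlist(lm))), 30)
  expect_true(all(c(107, 10, 9) %in% lm$forehead))
  expect_true(all(c(118, 50) %in% lm$left_cheek))
  expect_true(all(c(347, 280) %in% lm$right_cheek))
})
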