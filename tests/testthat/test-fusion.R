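# Fusion model: configuration contracts, loss, training behaviour,
# determinism, cross-validation partitioning.

test_that("configuration invariants are enforced", {
  expect_error(fusion_config(block_cells = c(60, 90, 30, 1)), "decreasing")
  expect_error(fusion_config(block_cells = c(90, 60, 30, 2)), "single cell")
  expect_error(fusion_config(dropout = 1), "dropout")
  expect_error(fusion_config(loss_weights = c(0, 0)), "loss_weights")
  cfg <- fusion_config()
  expect_equal(cfg$block_cells, c(90L, 60L, 30L, 1L))
  expect_equal(cfg$window_len, 300L)
  expect_equal(cfg$in_channels, 4L)
})

test_that("the model accepts a window_len x 4 stack and emits one value per step", {
  cfg <- fusion_config(window_len = 60, seed = 1)
  m <- build_fusion_model(cfg)
  expect_length(m$weights$layers, 4)
  stack <- matrix(runif(60 * 4), 60, 4)
  expect_warning(out <- construct_rppg(m, stack), "not been trained")
  expect_s3_class(out, "pulse_signal")
  expect_length(out$samples, 60)
  expect_equal(out$label, "fused")
  out2 <- suppressWarnings(construct_rppg(m, stack))
  expect_identical(out$samples, out2$samples)    # inference is deterministic
  expect_error(suppressWarnings(construct_rppg(m, matrix(0, 50, 4))),
               "60 x 4")
})

test_that("the loss combines RMSE and correlation with the degeneracy rule", {
  t <- seq(0, 1, length.out = 50)
  expect_equal(fusion_loss(t, t), 0)
  # anti-correlated at the same scale: r = -1 contributes 2 per unit weight
  expect_equal(fusion_loss(1 - t, t, weights = c(0, 1)), 2)
  # constant prediction: maximal r penalty plus the RMSE term
  cn <- rep(0.5, 50)
  expect_equal(fusion_loss(cn, t, weights = c(1, 1)),
               rmse(cn, t) + 1)
  expect_gt(fusion_loss(rnorm(50), t), 0)
  expect_error(fusion_loss(1:5, 1:6), "length")
})

test_that("training solves the toy identity task", {
  pairs <- toy_pairs(40)
  cfg <- fusion_config(epochs = 25, batch_size = 16, dropout = 0.1, seed = 0)
  m <- train_fusion(build_fusion_model(cfg), pairs)
  log <- m$training_log
  expect_lt(min(log$val_loss), 0.25 * log$val_loss[1])
  expect_true(all(diff(log$lr) <= 0))           # scheduler never raises the lr
  held <- toy_pairs(8, seed = 99)
  arr <- array(0, dim = c(300, 4, 8))
  for (i in 1:8) arr[, , i] <- held[[i]]$inputs
  preds <- construct_rppg(m, arr)
  rs <- vapply(1:8, function(i)
    pearson_r(preds[[i]]$samples, held[[i]]$target), numeric(1))
  expect_gt(mean(rs), 0.9)
})

test_that("training is reproducible under a fixed seed", {
  pairs <- toy_pairs(12)
  cfg <- fusion_config(epochs = 3, batch_size = 4, seed = 5)
  m1 <- train_fusion(build_fusion_model(cfg), pairs)
  m2 <- train_fusion(build_fusion_model(cfg), pairs)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$training_log, m2$training_log)
})

test_that("cross-validation partitions by video without leakage", {
  pairs <- toy_pairs(20, T = 60)
  cfg <- fusion_config(window_len = 60, epochs = 2, batch_size = 8,
                       val_fraction = 0, seed = 3)
  cv <- crossvalidate_fusion(pairs, k = 5, config = cfg)
  folds <- cv$folds
  expect_length(folds, 20)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(as.vector(table(folds)), rep(4L, 5))   # 4 videos per test fold
  # a video's windows all share one fold
  vids <- vapply(pairs, `[[`, character(1), "video")
  expect_true(all(tapply(folds, vids, function(f) length(unique(f))) == 1))
  # every window is evaluated exactly once per method
  rows <- cv$report$rows
  fused_rows <- rows[rows$method == "fused", ]
  expect_equal(nrow(fused_rows), 20)
  expect_equal(anyDuplicated(fused_rows[, c("video", "window")]), 0)
  expect_error(crossvalidate_fusion(pairs[1:3], k = 5), "fewer")
})

test_that("window pairs carry aligned, normalized signals with provenance", {
  d <- make_dataset(list(activity_preset("rest", duration_s = 21, seed = 1),
                         activity_preset("talk", duration_s = 21, seed = 2)))
  pairs <- make_window_pairs(d)
  expect_length(pairs, 4)     # two 10-s windows per 21-s video
  p <- pairs[[1]]
  expect_equal(colnames(p$inputs), c("ica", "lgi", "chrom", "pos"))
  expect_equal(nrow(p$inputs), 300)
  expect_length(p$target, 300)
  rng <- range(p$inputs)
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  expect_gte(min(p$target), 0); expect_lte(max(p$target), 1)
  expect_equal(p$video, "video001")
  expect_equal(vapply(pairs, `[[`, character(1), "activity"),
               c("rest", "rest", "talk", "talk"))
})
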