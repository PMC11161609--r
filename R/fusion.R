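# Fusion model: a stacked-LSTM sequence model mapping the 4-channel
# extractor stack (ica, lgi, chrom, pos) of a 10-s window to a
# contact-like PPG waveform, trained with an RMSE + (1 - Pearson r) loss
# under grouped 5-fold cross-validation.

#' Fusion model configuration
#'
#' @param window_len Window length in samples (default 300 = 10 s at
#'   30 fps).
#' @param block_cells Recurrent state size of each LSTM block; strictly
#'   decreasing to 1 (default `c(90, 60, 30, 1)`, tapering from 90 to 1).
#' @param dropout Dropout probability between blocks in \[0, 1).
#' @param loss_weights Length-2 weights `(w_rmse, w_r)` of the
#'   `w_rmse * RMSE + w_r * (1 - r)` loss; non-negative, not both zero.
#' @param lr Initial Adam step size.
#' @param lr_factor,lr_patience,lr_floor Reduce-on-plateau schedule:
#'   multiply the step size by `lr_factor` after `lr_patience` epochs
#'   without validation improvement, never below `lr_floor`.
#' @param epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation improvement
#'   before stopping.
#' @param batch_size Mini-batch size.
#' @param val_fraction Fraction of training windows held out as the
#'   validation set monitored by the scheduler.
#' @param clip_norm Global gradient-norm clip (0 disables).
#' @param seed Integer seed controlling weight initialisation, dropout
#'   masks and epoch shuffles.
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(window_len = 300, block_cells = c(90, 60, 30, 1),
                          dropout = 0.2, loss_weights = c(rmse = 1, r = 1),
                          lr = 1e-3, lr_factor = 0.5, lr_patience = 5,
                          lr_floor = 1e-5, epochs = 100,
                          early_stop_patience = 15, batch_size = 32,
                          val_fraction = 0.15, clip_norm = 5, seed = 1L) {
  check_num(window_len, "window_len", lower = 2)
  if (length(block_cells) < 2 || any(diff(block_cells) >= 0))
    stop_cfg("block_cells", "must be strictly decreasing")
  if (block_cells[length(block_cells)] != 1)
    stop_cfg("block_cells", "must end in a single cell")
  if (any(block_cells < 1)) stop_cfg("block_cells", "must be positive")
  check_num(dropout, "dropout", lower = 0, upper = 1 - 1e-9)
  check_num(loss_weights, "loss_weights", lower = 0, len = 2L)
  if (sum(loss_weights) <= 0)
    stop_cfg("loss_weights", "must not both be zero")
  check_num(lr, "lr", lower = 1e-12)
  check_num(epochs, "epochs", lower = 1)
  check_num(batch_size, "batch_size", lower = 1)
  check_num(val_fraction, "val_fraction", lower = 0, upper = 0.5)
  structure(
    list(window_len = as.integer(window_len),
         in_channels = 4L,
         block_cells = as.integer(block_cells),
         dropout = dropout,
         loss_weights = unname(loss_weights),
         lr = lr, lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
         lr_floor = lr_floor, epochs = as.integer(epochs),
         early_stop_patience = as.integer(early_stop_patience),
         batch_size = as.integer(batch_size),
         val_fraction = val_fraction, clip_norm = clip_norm,
         seed = as.integer(seed)),
    class = "fusion_config")
}

init_weights <- function(config) {
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  with_seed(config$seed, {
    d <- config$in_channels
    layers <- lapply(config$block_cells, function(h) {
      W <- glorot(d, 4 * h)
      U <- glorot(h, 4 * h)
      b <- rep(0, 4 * h)
      b[(h + 1):(2 * h)] <- 1        # forget-gate bias at 1
      d <<- h
      list(W = W, U = U, b = b)
    })
    hl <- config$block_cells[length(config$block_cells)]
    list(layers = layers,
         dense = list(w = as.numeric(glorot(hl, 1)), b = 0))
  })
}

#' Build an untrained fusion model
#'
#' Architecture: one LSTM block (full-sequence output) plus dropout per
#' entry of `block_cells`, then a time-distributed affine (dense) head
#' producing one value per time step.
#'
#' @param config A [fusion_config()].
#' @return Object of class `fusion_model`.
#' @export
build_fusion_model <- function(config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  w <- init_weights(config)
  n_par <- sum(vapply(w$layers, function(l)
    length(l$W) + length(l$U) + length(l$b), numeric(1))) +
    length(w$dense$w) + 1
  structure(
    list(config = config, weights = w, trained = FALSE,
         n_parameters = n_par, training_log = NULL, fold_id = NA),
    class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %d LSTM blocks (%s cells) + dense, %d parameters, %s\n",
              length(x$config$block_cells),
              paste(x$config$block_cells, collapse = "-"),
              x$n_parameters,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Training loss
#'
#' `w_rmse * RMSE(pred, target) + w_r * (1 - r(pred, target))`. A
#' constant prediction (or target) makes the correlation undefined; the
#' r term then takes its maximal penalty 1.
#'
#' @param pred,target Equal-length numeric vectors (length >= 2).
#' @param weights Length-2 non-negative weights `(w_rmse, w_r)`.
#' @return Non-negative scalar; zero iff `pred` equals `target`.
#' @export
fusion_loss <- function(pred, target, weights = c(1, 1)) {
  pred <- as_samples(pred); target <- as_samples(target)
  if (length(pred) != length(target)) stop("fusion_loss: length mismatch")
  if (length(pred) < 2) stop("fusion_loss: need at least 2 samples")
  r <- pearson_r(pred, target)
  rterm <- if (is.na(r)) 1 else 1 - r
  weights[1] * rmse(pred, target) + weights[2] * rterm
}

# window pairs -> (T x 4 x N) input array and (T x N) target matrix
pairs_to_arrays <- function(pairs, window_len) {
  n <- length(pairs)
  X <- array(NA_real_, dim = c(window_len, 4, n))
  Y <- matrix(NA_real_, window_len, n)
  for (i in seq_len(n)) {
    stopifnot(nrow(pairs[[i]]$inputs) == window_len)
    X[, , i] <- pairs[[i]]$inputs
    Y[, i] <- as_samples(pairs[[i]]$target)
  }
  list(X = X, Y = Y)
}

#' Train the fusion model
#'
#' Mini-batch Adam on the combined RMSE + (1 - r) loss, with
#' reduce-on-plateau learning-rate scheduling and early stopping
#' monitored on a held-out validation split of the training windows.
#' Fully seeded: the same seed and data give identical weights.
#'
#' @param model A [build_fusion_model()] output.
#' @param pairs List of window pairs (see [make_window_pairs()]): each
#'   has `inputs` (window_len x 4 matrix, min-max normalized) and
#'   `target` (normalized contact-PPG window).
#' @param val_pairs Optional explicit validation pairs; otherwise
#'   `val_fraction` of `pairs` is split off (seeded).
#' @return The model with trained weights and a `training_log`
#'   data.frame (epoch, train_loss, val_loss, lr).
#' @export
train_fusion <- function(model, pairs, val_pairs = NULL) {
  stopifnot(inherits(model, "fusion_model"))
  cfg <- model$config
  if (length(pairs) < 2) stop("train_fusion: need at least 2 windows")
  if (is.null(val_pairs)) {
    n_val <- floor(cfg$val_fraction * length(pairs))
    if (n_val > 0) {
      val_id <- with_seed(cfg$seed + 7L,
                          sample(length(pairs), n_val))
      val_pairs <- pairs[val_id]
      pairs <- pairs[-val_id]
    } else {
      val_pairs <- list()
    }
  }
  all_pairs <- c(pairs, val_pairs)
  arr <- pairs_to_arrays(all_pairs, cfg$window_len)
  hp <- list(epochs = cfg$epochs, batch_size = cfg$batch_size,
             lr = cfg$lr, lr_factor = cfg$lr_factor,
             lr_patience = cfg$lr_patience, lr_floor = cfg$lr_floor,
             early_stop_patience = cfg$early_stop_patience,
             w_rmse = cfg$loss_weights[1], w_r = cfg$loss_weights[2],
             dropout = cfg$dropout, clip_norm = cfg$clip_norm)
  res <- lstm_train_cpp(model$weights, arr$X, arr$Y,
                        seq_along(pairs),
                        if (length(val_pairs) > 0)
                          length(pairs) + seq_along(val_pairs) else integer(0),
                        hp, cfg$seed)
  model$weights <- res$weights
  model$trained <- TRUE
  model$training_log <- data.frame(
    epoch = seq_along(res$train_loss),
    train_loss = res$train_loss,
    val_loss = res$val_loss,
    lr = res$lr)
  model$best_epoch <- res$best_epoch
  model
}

#' Construct the fused rPPG for one or more windows
#'
#' Deterministic forward pass (dropout disabled) of the trained model.
#'
#' @param model A trained `fusion_model`.
#' @param stack Either a `window_len x 4` matrix (one window) or a
#'   `window_len x 4 x n` array; channels must be min-max normalized in
#'   the fixed (ica, lgi, chrom, pos) order.
#' @param rate Sampling rate attached to the output signal(s).
#' @return A [pulse_signal()] labelled `"fused"` (or a list of them).
#' @export
construct_rppg <- function(model, stack, rate = 30) {
  stopifnot(inherits(model, "fusion_model"))
  if (!model$trained) warning("model has not been trained")
  one <- FALSE
  if (is.matrix(stack)) {
    stack <- array(stack, dim = c(nrow(stack), ncol(stack), 1))
    one <- TRUE
  }
  d <- dim(stack)
  if (length(d) != 3 || d[1] != model$config$window_len || d[2] != 4)
    stop(sprintf("construct_rppg: expected a %d x 4 stack",
                 model$config$window_len))
  P <- lstm_predict_cpp(model$weights, stack)
  out <- lapply(seq_len(ncol(P)), function(i)
    pulse_signal(P[, i], rate = rate, label = "fused"))
  if (one) out[[1]] else out
}

#' Build training/evaluation window pairs from a synthetic dataset
#'
#' For each video: the RGB trace is cut into non-overlapping 10-s
#' windows; each window is run through the four input extractors (plus
#' the green baseline), the outputs are detrended, bandpassed
#' (0.65-4 Hz) and min-max normalized. The contact PPG is resampled to
#' the video frame rate, filtered the same way, windowed and normalized.
#'
#' @param dataset A [make_dataset()] result (or any list of samples with
#'   `rgb`, `cppg`, `video_id`, `activity`).
#' @param window_s Window length in seconds.
#' @param seed Seed forwarded to the ICA extractor.
#' @return List of window pairs; each has `inputs` (window_len x 4
#'   matrix, columns ica/lgi/chrom/pos), `baselines` (named list of
#'   normalized baseline signals, currently `green`), `target`
#'   (normalized cPPG window), `video`, `window`, `activity`, `fps`.
#' @export
make_window_pairs <- function(dataset, window_s = 10, seed = 1L) {
  out <- list()
  for (smp in dataset) {
    fps <- smp$rgb$fps
    wlen <- round(window_s * fps)
    cppg <- resample_to(smp$cppg, fps)
    cppg <- bandpass_signal(detrend_signal(cppg))
    cwins <- segment_windows(cppg, window_s)
    # window the raw RGB, extract per window
    n_win <- floor(nrow(smp$rgb$values) / wlen)
    n_win <- min(n_win, length(cwins))
    for (i in seq_len(n_win)) {
      rows <- ((i - 1) * wlen + 1):(i * wlen)
      wtrace <- rgb_trace(smp$rgb$values[rows, , drop = FALSE], fps = fps)
      stack <- extract_all(wtrace, seed = seed)
      stack <- apply(stack, 2, function(s) {
        s <- bandpass_signal(detrend_vec(s), rate = fps)
        minmax_normalize(s)$samples
      })
      green <- extract_green(wtrace)$samples
      green <- minmax_normalize(
        bandpass_signal(detrend_vec(green), rate = fps))$samples
      target <- minmax_normalize(cwins[[i]]$samples)$samples
      out[[length(out) + 1]] <- list(
        inputs = stack,
        baselines = list(green = green),
        target = target,
        video = smp$video_id, window = i,
        activity = smp$activity, fps = fps)
    }
  }
  if (length(out) == 0) stop("make_window_pairs: no complete windows")
  out
}

# seeded k-fold assignment of videos, balanced sizes
fold_assignment <- function(video_ids, k, seed) {
  uv <- unique(video_ids)
  if (length(uv) < k)
    stop(sprintf(paste0("crossvalidate: %d source videos but k = %d folds; ",
                        "reduce k or use window-level splitting"),
                 length(uv), k))
  ord <- with_seed(seed, sample(uv))
  fold_of <- rep(seq_len(k), length.out = length(uv))
  names(fold_of) <- ord
  fold_of[video_ids]
}

#' Grouped k-fold cross-validation of the fusion model
#'
#' Partitions windows into k folds grouped by source video (no video
#' spans folds, preventing leakage), trains the model from scratch on
#' each training split and evaluates the fused output — and every input
#' method plus the green baseline — on the held-out windows with all
#' four criteria.
#'
#' @param pairs Window pairs from [make_window_pairs()].
#' @param k Number of folds (default 5, i.e. 80/20 splits).
#' @param config A [fusion_config()].
#' @param by_video Group folds by video (default). `FALSE` restores
#'   naive window-level splitting.
#' @return Object of class `cv_report`: `folds` (per-window fold id),
#'   `report` (a [evaluate_windows()] metric report over all held-out
#'   windows and methods), `models` (one trained model per fold),
#'   `config`.
#' @export
crossvalidate_fusion <- function(pairs, k = 5, config = fusion_config(),
                                 by_video = TRUE) {
  if (length(pairs) < k) stop("crossvalidate: fewer windows than folds")
  vids <- vapply(pairs, `[[`, character(1), "video")
  folds <- if (by_video) {
    fold_assignment(vids, k, config$seed)
  } else {
    with_seed(config$seed, sample(rep(seq_len(k), length.out = length(pairs))))
  }
  eval_pairs <- list()
  models <- vector("list", k)
  for (fold in seq_len(k)) {
    test_id <- which(folds == fold)
    train_id <- which(folds != fold)
    cfg <- config
    cfg$seed <- config$seed + fold
    model <- build_fusion_model(cfg)
    model <- train_fusion(model, pairs[train_id])
    model$fold_id <- fold
    models[[fold]] <- model
    arr <- pairs_to_arrays(pairs[test_id], config$window_len)
    P <- lstm_predict_cpp(model$weights, arr$X)
    for (j in seq_along(test_id)) {
      p <- pairs[[test_id[j]]]
      base <- list(video = p$video, window = p$window,
                   activity = p$activity, rate = p$fps,
                   target = p$target)
      # evaluate the fused window under the same per-window min-max
      # normalization applied to every competing method
      eval_pairs[[length(eval_pairs) + 1]] <-
        c(base, list(method = "fused", pred = minmax_normalize(P[, j])$samples))
      for (m in colnames(p$inputs))
        eval_pairs[[length(eval_pairs) + 1]] <-
          c(base, list(method = m, pred = p$inputs[, m]))
      for (m in names(p$baselines))
        eval_pairs[[length(eval_pairs) + 1]] <-
          c(base, list(method = m, pred = p$baselines[[m]]))
    }
  }
  structure(
    list(folds = folds, report = evaluate_windows(eval_pairs),
         models = models, config = config, k = k),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> k=%d folds over %d windows\n",
              x$k, length(x$folds)))
  print(x$report)
  invisible(x)
}

#' Run the documented synthetic fusion benchmark
#'
#' The package's self-contained benchmark: a seeded synthetic corpus
#' spanning the five activity regimes (one 10-s window per video), the
#' full window-pair pipeline, grouped 5-fold cross-validation of the
#' fusion model, and the per-method metric report over all held-out
#' windows.
#'
#' @param seed Master seed; per-video seeds and the model seed derive
#'   from it.
#' @param n_per_activity Videos per activity.
#' @param activities Activity regimes to include.
#' @param duration_s Per-video duration in seconds.
#' @param epochs Training epoch budget per fold.
#' @param k Folds.
#' @param ... Additional overrides passed to [fusion_config()].
#' @return A `cv_report`.
#' @export
run_synthetic_benchmark <- function(seed = 1L, n_per_activity = 7,
                                    activities = c("rest", "talk",
                                                   "translation", "rotation",
                                                   "gym"),
                                    duration_s = 21, epochs = 100, k = 5,
                                    ...) {
  cfgs <- list()
  i <- 0L
  for (act in activities) {
    for (j in seq_len(n_per_activity)) {
      i <- i + 1L
      cfgs[[i]] <- activity_preset(act, duration_s = duration_s,
                                   seed = seed * 1000L + i)
    }
  }
  dataset <- make_dataset(cfgs)
  pairs <- make_window_pairs(dataset, seed = seed)
  config <- fusion_config(epochs = epochs, batch_size = 16, dropout = 0.1,
                          lr = 2e-3, lr_patience = 10,
                          early_stop_patience = 30, val_fraction = 0.1,
                          seed = seed, ...)
  crossvalidate_fusion(pairs, k = k, config = config)
}
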