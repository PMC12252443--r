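#' Fit per-attribute min-max normalization bounds
#'
#' @param curves A list of fermentation curves (or a single data.frame); all
#'   six attributes are used.
#' @param attributes Attribute columns to normalize (default the six curve
#'   channels).
#' @return A data.frame with columns `attribute`, `min`, `max`.  Constant
#'   attributes get their upper bound widened by 1e-9 with a warning.
#' @export
minmax_fit <- function(curves, attributes = curve_attributes()) {
  if (is.data.frame(curves)) curves <- list(curves)
  pooled <- do.call(rbind, lapply(curves, function(cv) {
    as.data.frame(cv)[, attributes, drop = FALSE]
  }))
  lo <- vapply(pooled, min, numeric(1))
  hi <- vapply(pooled, max, numeric(1))
  flat <- hi <= lo
  if (any(flat)) {
    warning("constant attribute(s) ", paste(attributes[flat], collapse = ", "),
            "; widening bounds by 1e-9")
    hi[flat] <- lo[flat] + 1e-9
  }
  data.frame(attribute = attributes, min = unname(lo), max = unname(hi))
}

#' Apply min-max normalization
#'
#' Maps the fitted range onto \code{[0, 1]} per attribute; values outside the
#' fitted range extrapolate linearly beyond \code{[0, 1]} (no clipping).
#'
#' @param values A data.frame or matrix whose columns match
#'   `bounds$attribute` (by name for data.frames, by position otherwise).
#' @param bounds Bounds from [minmax_fit()].
#' @return Normalized values, same shape.
#' @export
minmax_apply <- function(values, bounds) {
  m <- as.matrix(as.data.frame(values)[, bounds$attribute, drop = FALSE])
  if (ncol(m) != nrow(bounds)) stop("attribute count does not match bounds")
  sweep(sweep(m, 2, bounds$min, `-`), 2, bounds$max - bounds$min, `/`)
}

#' Invert min-max normalization
#'
#' @param normalized Normalized values (matrix or data.frame, columns in
#'   bounds order).
#' @param bounds Bounds from [minmax_fit()].
#' @return Values on the original scale; `minmax_invert(minmax_apply(x))`
#'   recovers `x` to within 1e-9.
#' @export
minmax_invert <- function(normalized, bounds) {
  m <- as.matrix(normalized)
  if (ncol(m) != nrow(bounds)) stop("attribute count does not match bounds")
  out <- sweep(sweep(m, 2, bounds$max - bounds$min, `*`), 2, bounds$min, `+`)
  colnames(out) <- bounds$attribute
  out
}

#' Build a windowed forecasting dataset from fermentation curves
#'
#' Slides a history/label window pair along every curve: window `i` takes
#' rows `[i, i + nt)` as input and rows `[i + nt, i + nt + pl)` as label, at
#' offsets 0, stride, 2 stride, ...  Values are min-max normalized with
#' bounds fitted on the supplied curves (or externally supplied bounds).
#'
#' @param curves List of fermentation curves.
#' @param nt History window length (time steps).
#' @param pl Prediction window length (time steps).
#' @param stride Offset between consecutive windows (default `pl`).
#' @param bounds Optional pre-fitted [minmax_fit()] bounds.
#' @param attributes Attribute columns (default the six channels).
#' @return A list of class `windowed_dataset` with `inputs` (array
#'   nt x k x n), `labels` (array pl x k x n), `bounds`, `window_curve`
#'   (source-curve index per window), `window_offset`, and `nt`, `pl`, `k`.
#' @export
make_windows <- function(curves, nt, pl, stride = pl, bounds = NULL,
                         attributes = curve_attributes()) {
  if (is.data.frame(curves)) curves <- list(curves)
  stopifnot(nt >= 1, pl >= 1, stride >= 1)
  if (is.null(bounds)) bounds <- minmax_fit(curves, attributes)
  k <- length(attributes)

  inputs <- list(); labels <- list(); wc <- integer(); wo <- integer()
  for (ci in seq_along(curves)) {
    norm <- minmax_apply(curves[[ci]], bounds)
    T_len <- nrow(norm)
    if (T_len < nt + pl) {
      warning("curve ", ci, " shorter than nt + pl; skipped")
      next
    }
    offsets <- seq(0, T_len - nt - pl, by = stride)
    for (off in offsets) {
      inputs[[length(inputs) + 1]] <- norm[(off + 1):(off + nt), , drop = FALSE]
      labels[[length(labels) + 1]] <-
        norm[(off + nt + 1):(off + nt + pl), , drop = FALSE]
      wc <- c(wc, ci); wo <- c(wo, off)
    }
  }
  n <- length(inputs)
  X <- array(0, dim = c(nt, k, n))
  Y <- array(0, dim = c(pl, k, n))
  for (i in seq_len(n)) { X[, , i] <- inputs[[i]]; Y[, , i] <- labels[[i]] }
  structure(list(inputs = X, labels = Y, bounds = bounds,
                 window_curve = wc, window_offset = wo,
                 nt = nt, pl = pl, k = k),
            class = "windowed_dataset")
}

# Subset a windowed dataset by window index.
subset_windows <- function(ds, idx) {
  structure(list(inputs = ds$inputs[, , idx, drop = FALSE],
                 labels = ds$labels[, , idx, drop = FALSE],
                 bounds = ds$bounds, window_curve = ds$window_curve[idx],
                 window_offset = ds$window_offset[idx],
                 nt = ds$nt, pl = ds$pl, k = ds$k),
            class = "windowed_dataset")
}

n_windows <- function(ds) dim(ds$inputs)[3]

#' Build a variable-depth LSTM forecaster
#'
#' Constructs the sequence-to-sequence model: `l` stacked LSTM layers of
#' `nc` cells (all but the last returning full sequences), a dense layer
#' mapping the final hidden state to `k * nc` units (ReLU), a dense layer to
#' `pl * k` outputs reshaped to `(pl, k)`, and optionally a
#' batch-normalization over the `k` output channels (batch statistics during
#' training, running statistics at inference).  The training loss is RMSE on
#' min-max-normalized labels.
#'
#' @param nc LSTM cells per layer (>= 1).
#' @param l Number of stacked LSTM layers (>= 1).
#' @param nt History window length.
#' @param pl Prediction window length.
#' @param k Number of attributes.
#' @param batchnorm Apply output batch-normalization (default TRUE).
#' @param seed Integer seed for weight initialisation and batch shuffling.
#' @return A list of class `vlstm_model` holding the model handle and its
#'   architecture.
#' @export
build_model <- function(nc, l, nt, pl, k = 6, batchnorm = TRUE, seed = 1) {
  stopifnot(nc >= 1, l >= 1, nt >= 1, pl >= 1, k >= 1)
  ptr <- vlstm_create(as.integer(nc), as.integer(l), as.integer(nt),
                      as.integer(pl), as.integer(k), isTRUE(batchnorm),
                      as.integer(seed))
  structure(list(ptr = ptr, nc = nc, l = l, nt = nt, pl = pl, k = k,
                 batchnorm = isTRUE(batchnorm), seed = seed),
            class = "vlstm_model")
}

#' Number of trainable parameters in the recurrent stack
#'
#' Standard LSTM count: `4 ((in + nc) nc + nc)` per layer, with `in = k` for
#' the first layer and `nc` above.
#'
#' @param model A `vlstm_model`.
#' @return Integer parameter count of the LSTM layers.
#' @export
lstm_param_count <- function(model) {
  ins <- c(model$k, rep(model$nc, model$l - 1))
  sum(4 * ((ins + model$nc) * model$nc + model$nc))
}

#' Training configuration for the forecaster
#'
#' Defaults follow the full-scale training protocol: Adam starting at 1e-4
#' with plateau-triggered reduction by a factor of 0.25 (patience 1 epoch)
#' down to 1e-10, early stopping with patience 5 and min_delta 1e-5
#' restoring the best weights, batch 32, up to 100 epochs, 20% validation
#' split.
#'
#' @param batch Minibatch size.
#' @param max_epochs Maximum epochs per fit.
#' @param lr_initial,lr_min,lr_factor,lr_patience Learning-rate schedule.
#' @param early_stop_patience,early_stop_min_delta Early stopping.
#' @param val_split Fraction of windows held out for validation.
#' @return A list of class `training_config`.
#' @export
training_config <- function(batch = 32, max_epochs = 100,
                            lr_initial = 1e-4, lr_min = 1e-10,
                            lr_factor = 0.25, lr_patience = 1,
                            early_stop_patience = 5,
                            early_stop_min_delta = 1e-5,
                            val_split = 0.2) {
  stopifnot(lr_factor > 0, lr_factor < 1, lr_min < lr_initial,
            val_split > 0, val_split < 1)
  structure(list(batch = batch, max_epochs = max_epochs,
                 lr_initial = lr_initial, lr_min = lr_min,
                 lr_factor = lr_factor, lr_patience = lr_patience,
                 early_stop_patience = early_stop_patience,
                 early_stop_min_delta = early_stop_min_delta,
                 val_split = val_split),
            class = "training_config")
}

# Deterministic train/validation split of window indices.
split_validation <- function(n, val_split, seed) {
  idx <- with_seed(seed, sample.int(n))
  n_val <- max(1, floor(n * val_split))
  list(val = idx[seq_len(n_val)], train = idx[-seq_len(n_val)])
}

#' Fit a forecaster on a windowed dataset
#'
#' Trains with Adam on the RMSE loss, holding out a validation split for the
#' learning-rate plateau schedule and early stopping, and restores the best
#' validation weights at the end.  Calling it again continues training from
#' the current weights (continual training).
#'
#' @param model A `vlstm_model`.
#' @param data A `windowed_dataset`.
#' @param config A [training_config()].
#' @param epochs Optional cap overriding `config$max_epochs`.
#' @param lr Optional starting learning rate overriding `config$lr_initial`.
#' @param split_seed Seed for the validation split.
#' @param verbose Print per-epoch losses.
#' @return The model (invisibly), with a `history` data.frame (epoch,
#'   train/val RMSE, learning rate) attached to the returned list.
#' @export
fit_model <- function(model, data, config = training_config(),
                      epochs = config$max_epochs, lr = config$lr_initial,
                      split_seed = model$seed, verbose = FALSE) {
  n <- n_windows(data)
  if (n < 2) stop("need at least 2 windows to fit")
  sp <- split_validation(n, config$val_split, split_seed)
  Xtr <- data$inputs[, , sp$train, drop = FALSE]
  Ytr <- data$labels[, , sp$train, drop = FALSE]
  Xval <- data$inputs[, , sp$val, drop = FALSE]
  Yval <- data$labels[, , sp$val, drop = FALSE]

  best_val <- Inf; best_w <- NULL
  plateau <- 0; stall <- 0
  hist <- data.frame()
  for (ep in seq_len(epochs)) {
    tr_loss <- vlstm_train_epoch(model$ptr, Xtr, Ytr, config$batch, lr)
    pred <- vlstm_predict(model$ptr, Xval)
    val_loss <- rmse(Yval, pred)
    hist <- rbind(hist, data.frame(epoch = ep, train_rmse = tr_loss,
                                   val_rmse = val_loss, lr = lr))
    if (verbose) {
      message(sprintf("epoch %d: train %.5f val %.5f lr %.3g",
                      ep, tr_loss, val_loss, lr))
    }
    if (val_loss < best_val - config$early_stop_min_delta) {
      best_val <- val_loss
      best_w <- vlstm_get_weights(model$ptr)
      stall <- 0; plateau <- 0
    } else {
      stall <- stall + 1; plateau <- plateau + 1
      if (plateau >= config$lr_patience && lr > config$lr_min) {
        lr <- max(config$lr_min, lr * config$lr_factor)
        plateau <- 0
      }
      if (stall >= config$early_stop_patience) break
    }
  }
  if (!is.null(best_w)) vlstm_set_weights(model$ptr, best_w)
  model$history <- hist
  model$best_val <- best_val
  invisible(model)
}

#' Chunked continual training
#'
#' Trains sequentially over an ordered list of dataset chunks without
#' reinitialising weights between chunks; each chunk gets its own validation
#' split, early stopping and learning-rate schedule (restarted at
#' `config$lr_initial` per chunk).
#'
#' @param model A `vlstm_model`.
#' @param chunks List of `windowed_dataset` chunks (all normalized with the
#'   same global bounds).
#' @param config A [training_config()].
#' @param verbose Print progress.
#' @return The model with `chunk_history`: a data.frame of chunk, epochs run
#'   and final validation RMSE.
#' @export
train_chunked <- function(model, chunks, config = training_config(),
                          verbose = FALSE) {
  stopifnot(length(chunks) >= 1)
  rows <- list()
  for (i in seq_along(chunks)) {
    if (n_windows(chunks[[i]]) < 2) {
      warning("chunk ", i, " is empty or too small; skipped")
      next
    }
    model <- fit_model(model, chunks[[i]], config,
                       split_seed = model$seed + i, verbose = verbose)
    rows[[length(rows) + 1]] <- data.frame(
      chunk = i, epochs = nrow(model$history), val_rmse = model$best_val)
  }
  model$chunk_history <- do.call(rbind, rows)
  model
}

#' Forecast future fermentation values from a raw history window
#'
#' Normalizes the window with the fitted bounds, runs the model, and inverts
#' the normalization, returning raw-unit predictions of shape `(pl, k)`.
#'
#' @param model A trained `vlstm_model`.
#' @param window A matrix or data.frame of `nt` rows by `k` attribute
#'   columns in raw units.
#' @param bounds [minmax_fit()] bounds used at training time.
#' @return Matrix `(pl, k)` of predictions in raw units.
#' @export
forecast <- function(model, window, bounds) {
  w <- minmax_apply(window, bounds)
  if (nrow(w) != model$nt || ncol(w) != model$k) {
    stop("window shape does not match the model (nt x k)")
  }
  X <- array(w, dim = c(model$nt, model$k, 1))
  pred <- vlstm_predict(model$ptr, X)[, , 1]
  minmax_invert(pred, bounds)
}

#' Evaluate held-out forecast error
#'
#' Mean over windows of the per-window RMSE between predictions and labels
#' on the normalized scale.
#'
#' @param model A trained `vlstm_model`.
#' @param test A `windowed_dataset` of held-out windows.
#' @return Mean normalized RMSE.
#' @export
evaluate <- function(model, test) {
  n <- n_windows(test)
  if (n < 1) stop("empty test set")
  pred <- vlstm_predict(model$ptr, test$inputs)
  mean(vapply(seq_len(n), function(i) {
    rmse(test$labels[, , i], pred[, , i])
  }, numeric(1)))
}

#' Min-max weighted layer penalty
#'
#' Elementwise product of the min-max-normalized validation RMSE and the
#' min-max-normalized layer count: zero at the minimum-RMSE candidate and at
#' the shallowest candidate, bounded in \code{[0, 1]}.  Reported as a
#' diagnostic alongside depth tuning to expose how much accuracy deeper
#' stacks buy per added layer.
#'
#' @param rmse_per_layer Validation RMSE per candidate (length >= 2).
#' @param layers Candidate layer counts, same length.
#' @return Penalties in \code{[0, 1]}; all zeros (with a warning) when the
#'   RMSE list is constant.
#' @export
weighted_layer_loss <- function(rmse_per_layer, layers) {
  if (length(rmse_per_layer) != length(layers) || length(layers) < 2) {
    stop("need two equal-length candidate lists")
  }
  rr <- diff(range(rmse_per_layer))
  lr <- diff(range(layers))
  if (rr == 0 || lr == 0) {
    warning("constant candidate list; penalties undefined, returning zeros")
    return(rep(0, length(layers)))
  }
  ((rmse_per_layer - min(rmse_per_layer)) / rr) *
    ((layers - min(layers)) / lr)
}

# Validation RMSE of a candidate architecture after a short training run.
tune_eval <- function(nc, l, data, epochs, seed, config, raw_scale) {
  model <- build_model(nc, l, data$nt, data$pl, data$k, batchnorm = FALSE,
                       seed = seed)
  model <- fit_model(model, data, config, epochs = epochs,
                     split_seed = seed)
  val <- model$best_val
  if (raw_scale) {
    # validation RMSE on the raw attribute scale instead of [0,1]
    sp <- split_validation(n_windows(data), config$val_split, seed)
    pred <- vlstm_predict(model$ptr, data$inputs[, , sp$val, drop = FALSE])
    span <- data$bounds$max - data$bounds$min
    err <- 0; ntot <- 0
    for (i in seq_along(sp$val)) {
      r <- (pred[, , i] - data$labels[, , sp$val[i]]) *
        matrix(span, data$pl, data$k, byrow = TRUE)
      err <- err + sum(r^2); ntot <- ntot + length(r)
    }
    val <- sqrt(err / ntot)
  }
  val
}

#' Random search over LSTM cell counts
#'
#' Samples `trials` unique cell counts from the 32-step grid within
#' `cell_range`, trains a 1-layer model for `epochs` epochs on each, and
#' selects the candidate with the minimum validation RMSE (ties broken
#' toward fewer cells).
#'
#' @param data A `windowed_dataset` (typically a fraction of the full set).
#' @param cell_range Inclusive search range (default c(32, 512)).
#' @param trials Number of unique candidates (default 10).
#' @param min_spacing Minimum distance between candidates (default 32; the
#'   grid step).
#' @param epochs Training epochs per candidate (default 10).
#' @param seed Search seed.
#' @param config Training configuration.
#' @param raw_scale Report validation RMSE on the raw attribute scale
#'   (default TRUE).
#' @return List with `best_cells` and `trace` (data.frame of candidate,
#'   val_rmse).
#' @export
tune_cells <- function(data, cell_range = c(32, 512), trials = 10,
                       min_spacing = 32, epochs = 10, seed = 1,
                       config = training_config(), raw_scale = TRUE) {
  grid <- seq(cell_range[1], cell_range[2], by = min_spacing)
  if (length(grid) < trials) {
    stop("infeasible search: fewer grid candidates than trials")
  }
  candidates <- sort(with_seed(seed, sample(grid, trials)))
  seeds <- child_seeds(seed, trials)
  val <- vapply(seq_along(candidates), function(i) {
    tune_eval(candidates[i], 1, data, epochs, seeds[i], config, raw_scale)
  }, numeric(1))
  ord <- order(val, candidates)  # ties -> fewer cells
  list(best_cells = candidates[ord[1]],
       trace = data.frame(cells = candidates, val_rmse = val))
}

#' Search over LSTM stack depth
#'
#' Trains a model of `best_cells` cells for every candidate depth, selects
#' the minimum validation RMSE (ties broken toward fewer layers), and
#' reports the min-max weighted layer penalty of every candidate as a
#' diagnostic.  Set `select = "penalty"` to pick the minimum-penalty depth
#' instead.
#'
#' @param data A `windowed_dataset`.
#' @param best_cells Cell count fixed by [tune_cells()].
#' @param layer_range Inclusive depth range (default c(1, 10)).
#' @param epochs Training epochs per candidate (default 10).
#' @param seed Search seed.
#' @param config Training configuration.
#' @param raw_scale Report validation RMSE on the raw attribute scale.
#' @param select `"rmse"` (default) or `"penalty"`.
#' @return List with `best_layers` and `trace` (layers, val_rmse, penalty).
#' @export
tune_layers <- function(data, best_cells, layer_range = c(1, 10),
                        epochs = 10, seed = 1, config = training_config(),
                        raw_scale = TRUE, select = c("rmse", "penalty")) {
  select <- match.arg(select)
  layers <- seq(layer_range[1], layer_range[2])
  seeds <- child_seeds(seed, length(layers))
  val <- vapply(seq_along(layers), function(i) {
    tune_eval(best_cells, layers[i], data, epochs, seeds[i], config,
              raw_scale)
  }, numeric(1))
  pen <- if (length(layers) >= 2 && diff(range(val)) > 0) {
    weighted_layer_loss(val, layers)
  } else rep(0, length(layers))
  crit <- if (select == "rmse") val else pen
  ord <- order(crit, layers)  # ties -> fewer layers
  list(best_layers = layers[ord[1]],
       trace = data.frame(layers = layers, val_rmse = val, penalty = pen))
}

#' Save / load forecaster weights
#'
#' Persists the architecture and weights; the compiled model is rebuilt on
#' load.
#'
#' @param model A `vlstm_model`.
#' @param path Destination file (RDS).
#' @export
save_model <- function(model, path) {
  saveRDS(list(nc = model$nc, l = model$l, nt = model$nt, pl = model$pl,
               k = model$k, batchnorm = model$batchnorm, seed = model$seed,
               weights = vlstm_get_weights(model$ptr)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  s <- readRDS(path)
  model <- build_model(s$nc, s$l, s$nt, s$pl, s$k, s$batchnorm, s$seed)
  vlstm_set_weights(model$ptr, s$weights)
  model
}

#' @export
print.vlstm_model <- function(x, ...) {
  cat(sprintf("<vlstm_model: %d layer(s) x %d cells, (%d x %d) -> (%d x %d)%s>\n",
              x$l, x$nc, x$nt, x$k, x$pl, x$k,
              if (x$batchnorm) ", output batch-norm" else ""))
  invisible(x)
}
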