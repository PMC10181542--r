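#' Class weights from positive-sample counts
#'
#' Inverse-log frequency weights `w_i = 1 / log(n_i)` computed from the
#' number of training records positive for each class: classes with many
#' positives get smaller weights, rare classes larger ones. The logarithm
#' base (natural by default) only rescales all weights uniformly.
#'
#' @param counts Positive-sample count per class (length 9; real values
#'   permitted). All counts must be at least 2 (`log(n) <= 0` below that).
#' @param base Logarithm base (default `exp(1)`).
#' @return Object of class `class_weights`: list with `w` and `n`.
#' @export
#' @examples
#' class_weights(c(1894, 1590, 496, 2496, 1370, 1280, 1722, 1560, 2663))
class_weights <- function(counts, base = exp(1)) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 2))
    stopf("all class counts must be finite and >= 2")
  w <- 1 / log(counts, base = base)
  if (!is.null(names(counts))) names(w) <- names(counts)
  structure(list(w = w, n = counts), class = "class_weights")
}

#' Weighted multi-label cross-entropy
#'
#' `L = sum_i -w_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]` over the
#' classes, with probabilities clipped to `[eps, 1 - eps]` so the loss stays
#' finite at the vertices.
#'
#' @param yhat Predicted probabilities (vector, or `N x C` matrix).
#' @param y True 0/1 labels, same shape.
#' @param w Per-class weights: a [class_weights()] object, a numeric vector,
#'   or `NULL` for unweighted (all 1) binary cross-entropy.
#' @param eps Clipping constant (default 1e-7).
#' @return For vector input, the scalar loss; for matrix input, the mean
#'   per-record loss.
#' @export
weighted_bce <- function(yhat, y, w = NULL, eps = 1e-7) {
  if (inherits(w, "class_weights")) w <- w$w
  if (is.null(dim(yhat))) { yhat <- rbind(yhat); y <- rbind(y) }
  stopifnot(all(dim(yhat) == dim(y)))
  if (is.null(w)) w <- rep(1, ncol(yhat))
  p <- pmin(pmax(yhat, eps), 1 - eps)
  per_class <- -(y * log(p) + (1 - y) * log(1 - p))
  mean(per_class %*% w)
}

#' Gradient of the weighted cross-entropy in the probabilities
#'
#' Analytic `dL/dyhat` for [weighted_bce()] at interior points (no clipping
#' active); used by the finite-difference gradient checks and, through the
#' sigmoid, by the training loop (`dL/dlogit = w_i (p_i - y_i)`).
#'
#' @inheritParams weighted_bce
#' @return Array of the same shape as `yhat`.
#' @export
weighted_bce_grad <- function(yhat, y, w = NULL, eps = 1e-7) {
  if (inherits(w, "class_weights")) w <- w$w
  vec <- is.null(dim(yhat))
  if (vec) { yhat <- rbind(yhat); y <- rbind(y) }
  if (is.null(w)) w <- rep(1, ncol(yhat))
  p <- pmin(pmax(yhat, eps), 1 - eps)
  g <- (-(y / p) + (1 - y) / (1 - p)) / nrow(yhat)
  g <- sweep(g, 2L, w, "*")
  g[yhat < eps | yhat > 1 - eps] <- 0
  if (vec) g[1L, ] else g
}

#' Training configuration
#'
#' @param lr Initial learning rate (default 0.001).
#' @param decay_factor Multiplicative decay (default 0.5).
#' @param decay_every Epochs between decays (default 10).
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 64).
#' @param seed RNG seed controlling shuffling, dropout and initialization.
#' @param threshold Probability threshold for multi-hot decisions.
#' @param weighted Use the class-frequency-weighted loss (`TRUE`, default)
#'   or plain binary cross-entropy.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, decay_factor = 0.5, decay_every = 10L,
                         epochs = 50L, batch_size = 64L, seed = 1L,
                         threshold = 0.5, weighted = TRUE) {
  stopifnot(lr > 0, decay_factor > 0, decay_factor < 1, epochs >= 1)
  structure(list(lr = lr, decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 threshold = threshold, weighted = weighted),
            class = "train_config")
}

#' Learning rate at an epoch
#'
#' Step schedule: `lr0 * decay_factor^floor((epoch - 1) / decay_every)` —
#' with the defaults, the rate halves after every tenth epoch.
#'
#' @param epoch Epoch number (1-based).
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
#' @examples
#' lr_at(1, train_config())   # 0.001
#' lr_at(11, train_config())  # 0.0005
lr_at <- function(epoch, cfg = train_config()) {
  stopifnot(epoch >= 1)
  cfg$lr * cfg$decay_factor^((epoch - 1) %/% cfg$decay_every)
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    path <- param_path(nm)
    params[[path]] <- params[[path]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Build model inputs from records
#'
#' Denoises, length-normalizes and spectrogram-transforms a list of records
#' into the batched arrays the network consumes, using the durations and
#' spectrogram settings of the model configuration.
#'
#' @param records List of [ecg_record] objects.
#' @param cfg A [model_config()] (supplies fs, duration, STFT window/hop and
#'   map size).
#' @param denoise Apply [denoise()] first (default TRUE).
#' @param progress Print a dot every 50 records.
#' @return List with `x1` (`T x 12 x N`), `x2` (`S x S x 12 x N`), `y`
#'   (`N x 9` multi-hot matrix) and `ids`.
#' @export
prepare_model_inputs <- function(records, cfg, denoise = TRUE,
                                 progress = FALSE) {
  n <- length(records)
  x1 <- array(0, c(cfg$input_len, cfg$in_leads, n))
  x2 <- array(0, c(cfg$map_size, cfg$map_size, cfg$in_leads, n))
  y <- matrix(0L, n, 9L, dimnames = list(NULL, class_vocabulary()))
  ids <- character(n)
  for (i in seq_len(n)) {
    rec <- records[[i]]
    if (rec$fs != cfg$fs)
      stopf("record %s sampled at %g Hz but the model expects %g Hz",
            rec$record_id, rec$fs, cfg$fs)
    xi <- if (denoise) preprocess_record(rec, target_s = cfg$target_s)
          else structure(fix_length(rec$signal, rec$fs, cfg$target_s),
                         record_id = rec$record_id, fs = rec$fs,
                         class = "ecg_input1d")
    mi <- to_tfmap(xi, window_len = cfg$stft_window, hop = cfg$stft_hop,
                   size = cfg$map_size, fs = cfg$fs)
    x1[, , i] <- t(unclass(xi))
    x2[, , , i] <- aperm(unclass(mi), c(2L, 3L, 1L))
    y[i, ] <- rec$labels
    ids[i] <- rec$record_id
    if (progress && i %% 50L == 0L) cat(".")
  }
  if (progress) cat("\n")
  list(x1 = x1, x2 = x2, y = y, ids = ids)
}

slice_inputs <- function(data, idx) {
  list(x1 = data$x1[, , idx, drop = FALSE],
       x2 = data$x2[, , , idx, drop = FALSE],
       y = data$y[idx, , drop = FALSE],
       ids = data$ids[idx])
}

#' Train a model on one fold
#'
#' Minibatch Adam training with the step learning-rate schedule and the
#' class-frequency-weighted multi-label cross-entropy; the per-class weights
#' are recomputed from this fold's training labels (classes with fewer than
#' two positives fall back to the `n = 2` weight). After each epoch the
#' validation macro F1 is evaluated in inference mode and the best-scoring
#' epoch's weights are kept.
#'
#' @param model An `ecmam_model` from [build_model()].
#' @param train_data,val_data Input lists from [prepare_model_inputs()]
#'   (`val_data` may be `NULL`: the final model is then the last epoch).
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List: `model` (best checkpoint), `history` (data.frame with
#'   epoch, lr, train_loss, val_macro_f1), `best_epoch`, `weights`
#'   (the class-weight vector used).
#' @export
train_fold <- function(model, train_data, val_data = NULL,
                       cfg = train_config(), verbose = FALSE) {
  n <- nrow(train_data$y)
  if (n < 1L) stopf("empty training fold")
  use_1d <- !is.null(model$params$b1d)
  use_2d <- !is.null(model$params$b2d)
  counts <- colSums(train_data$y)
  w <- if (cfg$weighted) class_weights(pmax(counts, 2))$w
       else rep(1, ncol(train_data$y))
  flat <- flatten_params(model$params)
  state <- adam_init(flat)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_macro_f1 = numeric())
  best <- list(f1 = -Inf, model = clone_model(model), epoch = 0L)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lr_at(epoch, cfg)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        yb <- train_data$y[idx, , drop = FALSE]
        fwd <- model_forward(
          model,
          x1 = if (use_1d) train_data$x1[, , idx, drop = FALSE],
          x2 = if (use_2d) train_data$x2[, , , idx, drop = FALSE],
          training = TRUE, keep_caches = TRUE)
        p <- pmin(pmax(fwd$probs, 1e-7), 1 - 1e-7)
        loss <- mean((-(yb * log(p) + (1 - yb) * log(1 - p))) %*% w)
        losses <- c(losses, loss)
        dlogits <- t(sweep(fwd$probs - yb, 2L, w, "*")) / length(idx)
        grads <- flatten_params(model_backward(model, fwd, dlogits))
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
      }
      val_f1 <- NA_real_
      if (!is.null(val_data)) {
        probs <- predict_probs(model, val_data)
        pred <- (probs >= cfg$threshold) * 1L
        rep_ <- metrics(tally(pred, val_data$y), scores = NULL,
                        truth = val_data$y, quiet = TRUE)
        val_f1 <- rep_$macro[["f1"]]
        if (val_f1 > best$f1) {
          best$f1 <- val_f1
          best$model <- clone_model(model)
          best$epoch <- epoch
        }
      }
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     train_loss = mean(losses),
                                     val_macro_f1 = val_f1))
      if (verbose)
        cat(sprintf("epoch %2d  lr %.5f  loss %.4f  val F1 %s\n",
                    epoch, lr, mean(losses),
                    ifelse(is.na(val_f1), "-", sprintf("%.3f", val_f1))))
    }
  })
  if (is.null(val_data)) { best$model <- model; best$epoch <- cfg$epochs }
  list(model = best$model, history = hist, best_epoch = best$epoch,
       weights = w)
}

# Batched inference over an input list, chunked to bound memory.
predict_probs <- function(model, data, chunk = 64L) {
  n <- nrow(data$y)
  use_1d <- !is.null(model$params$b1d)
  use_2d <- !is.null(model$params$b2d)
  out <- matrix(0, n, model$cfg$n_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- model_forward(
      model,
      x1 = if (use_1d) data$x1[, , idx, drop = FALSE],
      x2 = if (use_2d) data$x2[, , , idx, drop = FALSE],
      training = FALSE)
  }
  colnames(out) <- class_vocabulary()[seq_len(model$cfg$n_classes)]
  out
}
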