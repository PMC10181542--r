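#' Fit an ECG arrhythmia classifier
#'
#' The package's main fitting function: takes labelled 12-lead records,
#' preprocesses them into the two model inputs (denoised fixed-length time
#' series and stacked STFT time-frequency maps), trains the requested network
#' variant with the class-frequency-weighted multi-label cross-entropy under
#' the step learning-rate schedule, and returns the checkpoint with the best
#' validation mean F1.
#'
#' @param records List of [ecg_record] objects (e.g. from [synth_dataset()]
#'   or [assemble_dataset()]), all sampled at the model configuration's rate.
#' @param variant Network variant: `"EC-MAM"` (default, dual branch with
#'   attention), `"1D-EC-SAM"`, `"2D-EC-SAM"` or `"EC-MMI"` (no attention).
#' @param model_cfg A [model_config()]; default is the CPU-sized tiny
#'   profile.
#' @param train_cfg A [train_config()].
#' @param val_records Optional held-out validation records. If `NULL`, a
#'   fraction `val_fraction` of `records` is split off at random (seeded by
#'   the training seed).
#' @param val_fraction Fraction used for validation when `val_records` is
#'   `NULL` (default 0.25).
#' @param verbose Print per-epoch progress.
#' @return Object of class `ecmam`: list with `model` (the best
#'   `ecmam_model`), `history` (per-epoch data.frame: epoch, lr, train_loss,
#'   val_macro_f1), `best_epoch`, `class_weights`, `threshold`, `n_train`,
#'   `n_val` and `call`. Methods: `print`, `summary`, `predict`, `plot`.
#' @export
#' @examples
#' \donttest{
#' ds <- synth_dataset(4, duration = c(10, 10), fs = 125, seed = 1)
#' fit <- ecmam(ds$records, train_cfg = train_config(epochs = 2,
#'                                                   batch_size = 8))
#' predict(fit, ds$records[1:2])
#' }
ecmam <- function(records, variant = "EC-MAM",
                  model_cfg = model_config("tiny"),
                  train_cfg = train_config(), val_records = NULL,
                  val_fraction = 0.25, verbose = FALSE) {
  stopifnot(length(records) >= 2L)
  if (is.null(val_records)) {
    n <- length(records)
    idx <- with_seed(train_cfg$seed, sample.int(n))
    n_val <- max(1L, floor(n * val_fraction))
    val_records <- records[idx[seq_len(n_val)]]
    records <- records[idx[-seq_len(n_val)]]
  }
  train_data <- prepare_model_inputs(records, model_cfg)
  val_data <- prepare_model_inputs(val_records, model_cfg)
  model <- build_model(variant, model_cfg, seed = train_cfg$seed)
  res <- train_fold(model, train_data, val_data, train_cfg,
                    verbose = verbose)
  structure(list(model = res$model, history = res$history,
                 best_epoch = res$best_epoch, class_weights = res$weights,
                 threshold = train_cfg$threshold,
                 n_train = length(records), n_val = length(val_records),
                 call = match.call()),
            class = "ecmam")
}

#' @export
print.ecmam <- function(x, ...) {
  cat(sprintf("Multimodal ECG classifier (%s, %s profile)\n",
              x$model$variant, x$model$cfg$profile))
  cat(sprintf("  trained on %d records (%d validation), %d epochs\n",
              x$n_train, x$n_val, nrow(x$history)))
  best <- x$history$val_macro_f1[x$best_epoch]
  cat(sprintf("  best epoch %d: validation macro F1 %.3f\n",
              x$best_epoch, best))
  invisible(x)
}

#' @export
summary.ecmam <- function(object, ...) {
  rr <- resource_report(object$model)
  cat(sprintf("%s / %s profile: %s trainable parameters (%.2f M)\n",
              object$model$variant, object$model$cfg$profile,
              format(rr$n_params, big.mark = ","), rr$params_m))
  cat(sprintf("forward MACs per record: %.3f G; checkpoint %.1f MB\n",
              rr$macs_g, rr$storage_mb))
  cat("class weights (1/log n):\n")
  print(round(object$class_weights, 4))
  cat("training history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Predict class probabilities or multi-hot labels
#'
#' @param object A fitted [ecmam()] classifier.
#' @param newdata List of [ecg_record] objects, or a prepared input list
#'   from [prepare_model_inputs()].
#' @param type `"prob"` for the `N x 9` probability matrix, `"class"` for
#'   the thresholded multi-hot matrix.
#' @param ... Unused.
#' @return Numeric matrix, records in rows, classes in vocabulary order.
#' @export
predict.ecmam <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "ecg_record")) newdata <- list(newdata)
  data <- if (is.list(newdata) && !is.null(newdata$x1)) newdata
          else prepare_model_inputs(newdata, object$model$cfg)
  probs <- predict_probs(object$model, data)
  rownames(probs) <- data$ids
  if (type == "prob") probs else (probs >= object$threshold) * 1L
}

#' Plot training history
#'
#' Training loss and validation macro F1 against the epoch, with the
#' selected best epoch marked.
#'
#' @param x A fitted [ecmam()] classifier.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ecmam <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  graphics::plot(h$epoch, h$val_macro_f1, type = "b", xlab = "epoch",
                 ylab = "validation macro F1", main = "model selection", ...)
  graphics::abline(v = x$best_epoch, lty = 2, col = "grey40")
  invisible(x)
}

#' Evaluate a fitted classifier on held-out records
#'
#' @param object A fitted [ecmam()] classifier.
#' @param records List of labelled [ecg_record] objects or a prepared input
#'   list.
#' @return A [metrics()] report (per-class and macro precision, recall, F1,
#'   AUC, accuracy, FNR, FPR).
#' @export
evaluate_model <- function(object, records) {
  stopifnot(inherits(object, "ecmam"))
  data <- if (is.list(records) && !is.null(records$x1)) records
          else prepare_model_inputs(records, object$model$cfg)
  probs <- predict_probs(object$model, data)
  pred <- (probs >= object$threshold) * 1L
  metrics(tally(pred, data$y), scores = probs, truth = data$y, quiet = TRUE)
}
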