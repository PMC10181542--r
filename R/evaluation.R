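#' One-vs-rest confusion counts per class
#'
#' @param pred `N x 9` 0/1 matrix of multi-hot predictions.
#' @param truth `N x 9` 0/1 matrix of true labels.
#' @return Object of class `class_counts`: data.frame with one row per class
#'   and columns TP, FP, TN, FN (each row sums to N).
#' @export
tally <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)))
    stopf("pred and truth must have identical shape")
  if (!all(pred %in% 0:1) || !all(truth %in% 0:1))
    stopf("pred and truth must be 0/1 matrices")
  tp <- colSums(pred == 1 & truth == 1)
  fp <- colSums(pred == 1 & truth == 0)
  tn <- colSums(pred == 0 & truth == 0)
  fn <- colSums(pred == 0 & truth == 1)
  cls <- colnames(truth)
  if (is.null(cls)) cls <- class_vocabulary()[seq_len(ncol(truth))]
  structure(data.frame(class = cls, TP = as.integer(tp), FP = as.integer(fp),
                       TN = as.integer(tn), FN = as.integer(fn),
                       row.names = NULL),
            class = c("class_counts", "data.frame"))
}

# Trapezoidal ROC area over unique score thresholds (one-vs-rest).
roc_auc <- function(scores, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l == 1); cum_fp <- cumsum(l == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)   # keep last index of tied scores
  tpr <- c(0, cum_tp[last] / np)
  fpr <- c(0, cum_fp[last] / nn)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Per-class and macro classification metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, one-vs-rest accuracy
#' `(TP+TN)/N`, F1 (harmonic mean of precision and recall), false-negative
#' rate `FN/(FN+TP)`, false-positive rate `FP/(FP+TN)`, and (when scores are
#' supplied) one-vs-rest ROC AUC by the trapezoidal rule. Macro values are
#' unweighted means over classes. Zero-denominator metrics are reported as 0
#' with a warning naming the classes affected.
#'
#' @param counts A [tally()] result.
#' @param scores Optional `N x 9` probability matrix for AUC.
#' @param truth Required with `scores`: the `N x 9` truth matrix.
#' @param quiet Suppress the zero-denominator warning.
#' @return Object of class `metrics_report`: list with `per_class`
#'   (data.frame) and `macro` (named numeric vector).
#' @export
metrics <- function(counts, scores = NULL, truth = NULL, quiet = FALSE) {
  stopifnot(inherits(counts, "class_counts"))
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  degenerate <- character(0)
  with(counts, {
    n <- TP + FP + TN + FN
    precision <- safe_div(TP, TP + FP)
    recall <- safe_div(TP, TP + FN)
    accuracy <- safe_div(TP + TN, n)
    f1 <- safe_div(2 * precision * recall, precision + recall)
    fnr <- safe_div(FN, FN + TP)
    fpr <- safe_div(FP, FP + TN)
    degenerate <<- counts$class[(TP + FP) == 0 | (TP + FN) == 0 |
                                  (precision + recall) == 0]
    auc <- rep(NA_real_, nrow(counts))
    if (!is.null(scores)) {
      stopifnot(!is.null(truth), ncol(scores) == nrow(counts))
      auc <- vapply(seq_len(ncol(scores)), function(k)
        roc_auc(scores[, k], truth[, k]), 0)
      auc[is.na(auc)] <- 0
    }
    per_class <- data.frame(class = counts$class, precision = precision,
                            recall = recall, f1 = f1, auc = auc,
                            accuracy = accuracy, fnr = fnr, fpr = fpr)
    macro <- c(precision = mean(precision), recall = mean(recall),
               f1 = mean(f1), auc = mean(auc), accuracy = mean(accuracy),
               fnr = mean(fnr), fpr = mean(fpr))
    if (length(degenerate) && !quiet)
      warning(sprintf("zero-denominator metrics reported as 0 for: %s",
                      paste(unique(degenerate), collapse = ", ")),
              call. = FALSE)
    structure(list(per_class = per_class, macro = macro),
              class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  pc <- x$per_class
  pc[-1] <- lapply(pc[-1], round, digits)
  print.data.frame(pc, row.names = FALSE)
  cat("macro:", paste(sprintf("%s %.3f", names(x$macro), x$macro),
                      collapse = "  "), "\n")
  invisible(x)
}

#' Model resource accounting
#'
#' Trainable parameter count (by exhaustive enumeration of weight elements),
#' forward multiply-accumulate count (closed-form per-layer formulas over the
#' configured input shapes, one record), and checkpoint size measured from
#' the serialized model file.
#'
#' @param model An `ecmam_model`.
#' @return Object of class `resource_report`: list with `n_params`,
#'   `params_m` (millions), `macs`, `macs_g` (billions), `storage_mb`.
#' @export
resource_report <- function(model) {
  n_par <- n_parameters(model)
  macs <- count_macs(model)
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  saveRDS(model, tmp)
  structure(list(n_params = n_par, params_m = n_par / 1e6,
                 macs = macs, macs_g = macs / 1e9,
                 storage_mb = file.size(tmp) / 2^20),
            class = "resource_report")
}

#' @export
print.resource_report <- function(x, ...) {
  cat(sprintf("params %.2f M | forward MACs %.2f G | checkpoint %.1f MB\n",
              x$params_m, x$macs_g, x$storage_mb))
  invisible(x)
}

# Closed-form multiply-accumulate count of one forward pass (batch of one).
count_macs <- function(model) {
  cfg <- model$cfg
  total <- 0
  out_len <- function(Tin, k, s, p) (Tin + 2 * p - k) %/% s + 1
  branch_macs <- function(two_d) {
    acc <- 0
    sp <- if (two_d) c(cfg$map_size, cfg$map_size) else cfg$input_len
    kst <- if (two_d) cfg$stem2d_kernel else cfg$stem1d_kernel
    km <- if (two_d) cfg$kernel2d else cfg$kernel1d
    taps <- function(k) if (two_d) k * k else k
    L <- function(sp) prod(sp)
    shrink <- function(sp, k, s, p) {
      if (two_d) c(out_len(sp[1], k, s, p), out_len(sp[2], k, s, p))
      else out_len(sp, k, s, p)
    }
    cin <- cfg$in_leads
    sp <- shrink(sp, kst, 2, (kst - 1) %/% 2)
    acc <- acc + taps(kst) * cin * cfg$widths[1] * L(sp)
    cin <- cfg$widths[1]
    sp <- shrink(sp, 3, 2, 1)                  # stem max-pool
    for (s in 1:4) for (b in seq_len(cfg$stage_blocks[s])) {
      w <- cfg$widths[s]; cout <- w * cfg$expansion
      stride <- if (b == 1 && s > 1) 2 else 1
      acc <- acc + cin * w * L(sp)                       # 1x1 reduce
      spm <- shrink(sp, km, stride, (km - 1) %/% 2)
      acc <- acc + taps(km) * w * w * L(spm)             # middle conv
      acc <- acc + w * cout * L(spm)                     # 1x1 expand
      if (!is.null(model$params[[if (two_d) "b2d" else "b1d"]][[
            paste0("stage", s)]][[paste0("block", b)]]$att)) {
        cr <- max(1, cout %/% cfg$r)
        acc <- acc + 2 * cout * cr * (if (two_d) 2 else 1)  # excitation
        if (two_d) acc <- acc + cfg$k_spatial^2 * 2 * L(spm) # spatial conv
      }
      if (cin != cout || stride != 1)
        acc <- acc + cin * cout * L(spm)                 # projection
      cin <- cout
      sp <- spm
    }
    acc
  }
  if (!is.null(model$params$b1d)) total <- total + branch_macs(FALSE)
  if (!is.null(model$params$b2d)) total <- total + branch_macs(TRUE)
  in_dim <- cfg$widths[4] * cfg$expansion *
    ((!is.null(model$params$b1d)) + (!is.null(model$params$b2d)))
  total + in_dim * cfg$fusion_hidden + cfg$fusion_hidden * cfg$n_classes
}
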