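#' Run the full pipeline end to end
#'
#' Wires the stages together: data (synthetic generation or a directory of
#' WFDB records) -> fold plan -> preprocessing and spectrograms -> training
#' on the chosen cross-validation fold -> evaluation on the held-out test
#' half -> artifacts on disk. Every run writes a YAML config snapshot
#' sufficient to reproduce it; all randomness derives from `seed`.
#'
#' Artifacts written under `out_dir`: `config.yaml` (snapshot),
#' `fold_plan.yaml`, `manifest.csv` (record ids, labels, durations),
#' `history.csv` (per-epoch log), `checkpoint.rds` (best model),
#' `metrics.json` and `metrics_per_class.csv` (test-set report with
#' Precision/Recall/F1/AUC/ACC columns), and `report.txt`.
#'
#' @param out_dir Output directory (created; must not require privileges).
#' @param variant Model variant (see [build_model()]).
#' @param profile `"tiny"` or `"full"` model profile.
#' @param data_dir Optional directory of WFDB records to use instead of the
#'   synthetic generator.
#' @param n_per_class Synthetic records per class when generating.
#' @param duration Synthetic duration range in seconds.
#' @param fold Which of the five cross-validation folds is the validation
#'   fold.
#' @param train_cfg A [train_config()].
#' @param seed Master seed for generation, splitting and training.
#' @return Invisibly, a list with `metrics`, `fit`, and the artifact paths.
#' @export
run_pipeline <- function(out_dir, variant = "EC-MAM", profile = "tiny",
                         data_dir = NULL, n_per_class = 20L,
                         duration = c(10, 10), fold = 1L,
                         train_cfg = train_config(epochs = 5L,
                                                  batch_size = 32L),
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model_config(profile)
  stage <- "synth"
  res <- tryCatch({
    records <- if (is.null(data_dir)) {
      synth_dataset(n_per_class, duration, fs = cfg$fs, seed = seed)$records
    } else {
      assemble_dataset(data_dir)
    }
    manifest <- data.frame(
      record_id = vapply(records, `[[`, "", "record_id"),
      labels = vapply(records, function(r)
        paste(names(r$labels)[r$labels == 1], collapse = "+"), ""),
      duration_s = vapply(records, function(r) ncol(r$signal) / r$fs, 0))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)

    stage <- "split"
    plan <- make_fold_plan(records, seed = seed)
    yaml::write_yaml(list(seed = plan$seed, test_ids = plan$test_ids,
                          folds = plan$folds),
                     file.path(out_dir, "fold_plan.yaml"))
    ids <- vapply(records, `[[`, "", "record_id")
    val_ids <- plan$folds[[fold]]
    train_ids <- setdiff(unlist(plan$folds), val_ids)

    stage <- "preprocess"
    fit <- ecmam(records[ids %in% train_ids], variant = variant,
                 model_cfg = cfg, train_cfg = train_cfg,
                 val_records = records[ids %in% val_ids])
    utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    saveRDS(fit, file.path(out_dir, "checkpoint.rds"))

    stage <- "evaluate"
    rep_ <- evaluate_model(fit, records[ids %in% plan$test_ids])
    tab <- rep_$per_class[, c("class", "precision", "recall", "f1", "auc",
                              "accuracy")]
    names(tab) <- c("Classes", "Precision", "Recall", "F1", "AUC", "ACC")
    utils::write.csv(tab, file.path(out_dir, "metrics_per_class.csv"),
                     row.names = FALSE)
    writeLines(to_json(list(per_class = rep_$per_class,
                            macro = as.list(rep_$macro))),
               file.path(out_dir, "metrics.json"))

    stage <- "report"
    yaml::write_yaml(list(variant = variant, profile = profile,
                          seed = seed, fold = fold,
                          n_records = length(records),
                          train = unclass(train_cfg)),
                     file.path(out_dir, "config.yaml"))
    rl <- c(sprintf("variant: %s (profile %s)", variant, profile),
            sprintf("records: %d (test %d / train %d / val %d)",
                    length(records), length(plan$test_ids),
                    length(train_ids), length(val_ids)),
            sprintf("best epoch %d, validation macro F1 %.3f",
                    fit$best_epoch,
                    fit$history$val_macro_f1[fit$best_epoch]),
            sprintf("test macro: %s",
                    paste(sprintf("%s %.3f", names(rep_$macro), rep_$macro),
                          collapse = "  ")))
    writeLines(rl, file.path(out_dir, "report.txt"))
    list(metrics = rep_, fit = fit, dir = out_dir)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}

# Minimal JSON writer (numbers, strings, lists, data.frames).
to_json <- function(x, indent = "") {
  if (is.data.frame(x))
    return(to_json(lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])),
                   indent))
  if (is.list(x)) {
    nms <- names(x)
    inner <- paste0(indent, "  ")
    items <- vapply(seq_along(x), function(i) {
      v <- to_json(x[[i]], inner)
      if (is.null(nms) || nms[i] == "") v
      else paste0("\"", nms[i], "\": ", v)
    }, "")
    open <- if (is.null(nms)) "[" else "{"
    close <- if (is.null(nms)) "]" else "}"
    return(paste0(open, "\n", inner,
                  paste(items, collapse = paste0(",\n", inner)),
                  "\n", indent, close))
  }
  if (is.character(x)) return(paste0("\"", x, "\""))
  if (length(x) == 1L) return(format(x, digits = 10))
  paste0("[", paste(format(x, digits = 10), collapse = ", "), "]")
}
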