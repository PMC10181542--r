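#' Load all WFDB records in a directory
#'
#' Loads every `.hea`/`.dat` pair under `dir`. Records whose diagnosis codes
#' map to none of the nine classes are excluded with a warning naming them.
#'
#' @param dir Directory of WFDB-dialect records.
#' @param mapping Code mapping from [read_dx_mapping()].
#' @param source_db Source tag applied to all loaded records.
#' @return List of [ecg_record] objects.
#' @export
assemble_dataset <- function(dir, mapping = read_dx_mapping(),
                             source_db = "SYNTH") {
  heas <- sort(list.files(dir, pattern = "\\.hea$", full.names = TRUE))
  if (!length(heas)) stopf("no .hea files found in %s", dir)
  recs <- lapply(heas, load_record, mapping = mapping, source_db = source_db)
  unmapped <- vapply(recs, function(r) isTRUE(attr(r, "unmapped")), NA)
  if (any(unmapped)) {
    warning(sprintf("excluding %d record(s) with no mappable diagnosis code: %s",
                    sum(unmapped),
                    paste(vapply(recs[unmapped], `[[`, "", "record_id"),
                          collapse = ", ")), call. = FALSE)
    recs <- recs[!unmapped]
  }
  recs
}

#' Per-class, per-source dataset summary
#'
#' Counts, for every rhythm class, the number of records positive for it in
#' each source database, plus row/column totals. With multi-label records the
#' class-total column can exceed the record total.
#'
#' @param records List of [ecg_record] objects (may be empty).
#' @return List with `counts` (9 x n_sources+1 integer matrix, last column
#'   `Total`) and `n_records` (total record count).
#' @export
summarize_dataset <- function(records) {
  vocab <- class_vocabulary()
  if (!length(records)) {
    counts <- matrix(0L, nrow = 9L, ncol = 1L,
                     dimnames = list(vocab, "Total"))
    return(list(counts = counts, n_records = 0L))
  }
  src <- vapply(records, `[[`, "", "source_db")
  labs <- t(vapply(records, function(r) as.integer(r$labels), integer(9L)))
  sources <- unique(src)
  counts <- sapply(sources, function(s)
    colSums(labs[src == s, , drop = FALSE]))
  counts <- matrix(as.integer(counts), nrow = 9L,
                   dimnames = list(vocab, sources))
  counts <- cbind(counts, Total = as.integer(rowSums(counts)))
  list(counts = counts, n_records = length(records))
}

#' Train/validation/test partition plan
#'
#' Splits record ids into a held-out test half and five cross-validation
#' folds over the remainder, mirroring the 0.5:0.5 split plus five-fold
#' cross-validation design. On odd N the test set takes the ceiling; folds
#' are as even as possible with earlier folds larger. No stratification is
#' applied (the split is purely random).
#'
#' @param records List of [ecg_record] objects, or a character vector of ids.
#' @param seed Integer seed; the same seed always yields the same plan.
#' @param n_folds Number of cross-validation folds (default 5).
#' @return Object of class `fold_plan`: list with `test_ids`, `folds` (list
#'   of id vectors), and `seed`.
#' @export
make_fold_plan <- function(records, seed, n_folds = 5L) {
  ids <- if (is.character(records)) records
         else vapply(records, `[[`, "", "record_id")
  if (anyDuplicated(ids)) stopf("record ids must be unique")
  n <- length(ids)
  if (n < 10L) stopf("need at least 10 records to build a fold plan, got %d", n)
  with_seed(seed, {
    perm <- sample(ids)
    n_test <- ceiling(n / 2)
    test_ids <- sort(perm[seq_len(n_test)])
    rest <- perm[-seq_len(n_test)]
    m <- length(rest)
    base <- m %/% n_folds
    sizes <- rep(base, n_folds) + as.integer(seq_len(n_folds) <= m %% n_folds)
    folds <- split(rest, rep(seq_len(n_folds), times = sizes))
    names(folds) <- paste0("fold", seq_len(n_folds))
    structure(list(test_ids = test_ids,
                   folds = lapply(folds, sort), seed = seed),
              class = "fold_plan")
  })
}

#' Materialize a printed class-distribution table as stub records
#'
#' Builds `n_records` minimal records (one zero sample per lead) whose
#' multi-hot labels reproduce a stated per-class positive count, assigning
#' class positives cyclically so that every record carries at least one label
#' whenever the class counts sum to at least `n_records` (multi-label overlap
#' absorbs the excess). Useful for checking summary arithmetic against a
#' published pathology-distribution table without the underlying signals.
#'
#' @param class_counts Integer vector of length 9 (vocabulary order): number
#'   of records positive for each class.
#' @param n_records Total number of records for this source.
#' @param source_db Source tag for the stubs.
#' @param id_prefix Prefix for generated record ids.
#' @return List of [ecg_record] stubs.
#' @export
stub_records_from_counts <- function(class_counts, n_records,
                                     source_db = "SYNTH",
                                     id_prefix = source_db) {
  class_counts <- as.integer(class_counts)
  stopifnot(length(class_counts) == 9L, all(class_counts >= 0L),
            all(class_counts <= n_records))
  labs <- matrix(0L, nrow = n_records, ncol = 9L)
  start <- 0L
  for (k in seq_len(9L)) {
    nk <- class_counts[k]
    if (nk > 0L) {
      idx <- ((start + seq_len(nk) - 1L) %% n_records) + 1L
      labs[idx, k] <- 1L
      start <- (start + nk) %% n_records
    }
  }
  sig <- matrix(0, nrow = 12L, ncol = 1L)
  lapply(seq_len(n_records), function(i)
    ecg_record(sprintf("%s-%06d", id_prefix, i), sig, 500, labs[i, ],
               source_db = source_db))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d test, folds: %s (seed %d)\n",
              length(x$test_ids),
              paste(lengths(x$folds), collapse = "/"), x$seed))
  invisible(x)
}
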