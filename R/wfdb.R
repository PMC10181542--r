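#' ECG record container
#'
#' Constructs and validates an `ecg_record`: one 12-lead recording with its
#' signal matrix (leads x samples, millivolts), sampling rate, multi-hot
#' label vector over the nine-class vocabulary, and source database tag.
#'
#' @param record_id Record identifier string.
#' @param signal Numeric 12 x L matrix of amplitudes in millivolts, rows in
#'   standard lead order (I, II, III, aVR, aVL, aVF, V1-V6).
#' @param fs Sampling rate in Hz (positive scalar).
#' @param labels Integer 0/1 vector of length 9 in vocabulary order (may be
#'   named; names are checked if present).
#' @param source_db One of `"CPSC2018"`, `"CPSC2018-Extra"`, `"Georgia"`,
#'   `"SYNTH"`.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(record_id, signal, fs, labels,
                       source_db = c("SYNTH", "CPSC2018", "CPSC2018-Extra",
                                     "Georgia")) {
  source_db <- match.arg(source_db)
  assert_finite_matrix(signal, "signal")
  if (nrow(signal) != 12L) stopf("signal must have 12 leads, got %d", nrow(signal))
  if (ncol(signal) < 1L) stopf("signal must have at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("fs must be > 0")
  labels <- as.integer(labels)
  if (length(labels) != 9L || !all(labels %in% 0:1))
    stopf("labels must be a 0/1 vector of length 9")
  labels <- stats::setNames(labels, class_vocabulary())
  structure(list(record_id = as.character(record_id), signal = signal,
                 fs = fs, labels = labels, source_db = source_db),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> 12 x %d @ %g Hz (%.1f s), source %s\n",
              x$record_id, ncol(x$signal), x$fs, ncol(x$signal) / x$fs,
              x$source_db))
  pos <- names(x$labels)[x$labels == 1L]
  cat("  labels:", if (length(pos)) paste(pos, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

# ---- WFDB (PhysioNet-Challenge dialect) reader / writer --------------------
# Header (.hea): "<id> <nsig> <fs> <nsamp>" then one line per signal
# "<file> 16 <gain>/mV <res> <zero> <first> <checksum> <blocksize> <lead>",
# then "#Dx: code1,code2" comment lines. Signal file: interleaved
# little-endian int16, sample-major (format 16).

#' Load a WFDB-dialect ECG record
#'
#' Reads a PhysioNet-Challenge-style header/signal pair and returns an
#' [ecg_record]. Amplitudes are converted to millivolts with each lead's
#' gain and baseline; diagnosis codes on `#Dx:` comment lines are mapped to
#' the nine-class vocabulary.
#'
#' @param header_path Path to the `.hea` header file.
#' @param mapping Code mapping from [read_dx_mapping()].
#' @param source_db Source tag stored on the record.
#' @return An [ecg_record]. If no diagnosis code maps into the vocabulary the
#'   record is returned with all-zero labels and attribute `unmapped = TRUE`;
#'   [assemble_dataset()] drops such records with a warning.
#' @export
load_record <- function(header_path, mapping = read_dx_mapping(),
                        source_db = "SYNTH") {
  if (!file.exists(header_path)) stopf("header file not found: %s", header_path)
  lines <- readLines(header_path, warn = FALSE)
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(top) < 4L) stopf("malformed header line: %s", lines[1L])
  record_id <- top[1L]
  nsig <- as.integer(top[2L]); fs <- as.numeric(top[3L]); nsamp <- as.integer(top[4L])
  if (is.na(nsig) || is.na(fs) || is.na(nsamp))
    stopf("unparseable header counts in %s", header_path)
  if (nsig != 12L) stopf("expected 12 signal channels, header declares %d", nsig)
  sig_lines <- lines[2:(1L + nsig)]
  gain <- numeric(nsig); zero <- numeric(nsig); lead <- character(nsig)
  dat_file <- NA_character_
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(sig_lines[i]), "\\s+")[[1L]]
    if (length(f) < 5L) stopf("malformed signal line: %s", sig_lines[i])
    dat_file <- f[1L]
    if (f[2L] != "16") stopf("unsupported signal format '%s' (only 16)", f[2L])
    g <- suppressWarnings(as.numeric(sub("/mV$", "", f[3L])))
    if (is.na(g) || g <= 0) stopf("unparseable gain '%s'", f[3L])
    gain[i] <- g
    zero[i] <- as.numeric(f[5L])
    lead[i] <- f[length(f)]
  }
  dat_path <- file.path(dirname(header_path), dat_file)
  if (!file.exists(dat_path)) stopf("signal file not found: %s", dat_path)
  raw <- readBin(dat_path, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) != nsig * nsamp)
    stopf("signal file %s truncated: expected %d samples, got %d",
          dat_path, nsig * nsamp, length(raw))
  adu <- matrix(raw, nrow = nsig)          # interleaved sample-major
  mv <- (adu - zero) / gain
  dx <- grep("^#\\s*Dx:", lines, value = TRUE)
  codes <- character(0)
  if (length(dx))
    codes <- trimws(unlist(strsplit(sub("^#\\s*Dx:\\s*", "", dx), ",")))
  labels <- codes_to_labels(codes, mapping)
  rec <- ecg_record(record_id, mv, fs, labels, source_db)
  if (length(codes) && sum(labels) == 0L) attr(rec, "unmapped") <- TRUE
  rec
}

#' Save an ECG record in the WFDB dialect
#'
#' Writes `<dir>/<record_id>.hea` and `<dir>/<record_id>.dat` (format 16,
#' little-endian int16, gain 1000 adu/mV) with labels emitted as a `#Dx:`
#' comment using the first matching code per positive class in the mapping.
#'
#' @param rec An [ecg_record].
#' @param dir Output directory (created if needed).
#' @param gain ADU per millivolt used for quantization.
#' @param mapping Code mapping used to pick a representative code per class.
#' @return Invisibly, the header path.
#' @export
save_record <- function(rec, dir, gain = 1000,
                        mapping = read_dx_mapping()) {
  stopifnot(inherits(rec, "ecg_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nsamp <- ncol(rec$signal)
  adu <- round(rec$signal * gain)
  adu[adu > 32767] <- 32767; adu[adu < -32768] <- -32768
  hea <- file.path(dir, paste0(rec$record_id, ".hea"))
  datf <- paste0(rec$record_id, ".dat")
  leads <- standard_leads()
  sig_lines <- sprintf("%s 16 %g/mV 16 0 %d 0 0 %s",
                       datf, gain, as.integer(adu[, 1L]), leads)
  pos <- names(rec$labels)[rec$labels == 1L]
  codes <- vapply(pos, function(cl) names(mapping)[match(cl, mapping)], "")
  hdr <- c(sprintf("%s 12 %g %d", rec$record_id, rec$fs, nsamp), sig_lines)
  if (length(codes)) hdr <- c(hdr, paste0("#Dx: ", paste(codes, collapse = ",")))
  writeLines(hdr, hea)
  con <- file(file.path(dir, datf), "wb")
  on.exit(close(con))
  writeBin(as.integer(adu), con, size = 2L, endian = "little")
  invisible(hea)
}
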