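#' Denoise a 12-lead ECG signal
#'
#' Removes baseline drift and wide-band muscle (EMG) noise with a wavelet
#' threshold scheme, then suppresses mains interference with an IIR notch.
#' Per lead: the signal is reflect-padded to a power-of-two length and
#' decomposed with a periodized db6 wavelet transform; the approximation band
#' (below roughly `fs / 2^(levels+1)` Hz, about 1 Hz at 500 Hz) is zeroed to
#' remove drift; detail coefficients are shrunk with a soft-hard compromise
#' rule at the universal threshold `sigma * sqrt(2 log n)`, `sigma` estimated
#' by the median absolute deviation of the finest detail band. The notch is a
#' second-order IIR section (quality factor `q`) applied forward-backward so
#' the pass is zero-phase.
#'
#' @param signal Numeric leads x samples matrix (millivolts).
#' @param fs Sampling rate in Hz.
#' @param powerline_hz Mains frequency to notch (50 or 60 Hz typically).
#'   Must satisfy `fs > 2 * powerline_hz`.
#' @param wavelet Wavelet name (`"db6"` default).
#' @param levels Decomposition depth; `NULL` picks
#'   `round(log2(fs)) - 1` (8 at 500 Hz) so the zeroed approximation band
#'   stays below about 1 Hz.
#' @param threshold One of `"compromise"` (default), `"soft"`, `"hard"`.
#' @param alpha Compromise factor in \[0,1\]: kept coefficients are shrunk by
#'   `alpha * threshold` (0 = hard, 1 = soft).
#' @param q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return Matrix of the same shape as `signal`.
#' @export
denoise <- function(signal, fs, powerline_hz = 50, wavelet = "db6",
                    levels = NULL, threshold = c("compromise", "soft", "hard"),
                    alpha = 0.5, q = 30) {
  threshold <- match.arg(threshold)
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  assert_finite_matrix(signal, "signal")
  if (fs <= 2 * powerline_hz)
    stopf("fs (%g Hz) must exceed twice the notch frequency (%g Hz)",
          fs, powerline_hz)
  flt_len <- wt_filters(wavelet)$L
  if (ncol(signal) <= flt_len)
    stopf("signal length (%d) must exceed the wavelet filter length (%d)",
          ncol(signal), flt_len)
  out <- t(apply(signal, 1L, wavelet_denoise_lead, fs = fs,
                 wavelet = wavelet, levels = levels,
                 threshold = threshold, alpha = alpha))
  nf <- notch_coefficients(powerline_hz, fs, q)
  out <- t(apply(out, 1L, function(x)
    as.numeric(signal::filtfilt(nf$b, nf$a, x))))
  dimnames(out) <- dimnames(signal)
  out
}

wavelet_denoise_lead <- function(x, fs, wavelet, levels, threshold, alpha) {
  L <- length(x)
  n <- 2^ceiling(log2(L))
  if (n > L) {
    # reflect-pad the tail to the next power of two
    pad <- n - L
    refl <- rev(x)[seq_len(min(pad, L))]
    xp <- c(x, rep(refl, length.out = pad))
  } else xp <- x
  if (is.null(levels)) levels <- max(4L, round(log2(fs)) - 1L)
  levels <- min(levels, floor(log2(n)) - 1L)
  dec <- dwt_periodized(xp, levels, wavelet)
  dec$a[] <- 0                                   # baseline band
  sigma <- stats::median(abs(dec$d[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n))
  dec$d <- lapply(dec$d, shrink_coefficients, thr = thr,
                  mode = threshold, alpha = alpha)
  idwt_periodized(dec)[seq_len(L)]
}

shrink_coefficients <- function(d, thr, mode, alpha) {
  if (thr <= 0) return(d)
  keep <- abs(d) > thr
  out <- numeric(length(d))
  out[keep] <- switch(mode,
    hard = d[keep],
    soft = sign(d[keep]) * (abs(d[keep]) - thr),
    compromise = sign(d[keep]) * (abs(d[keep]) - alpha * thr))
  out
}

# Second-order IIR notch (constrained pole-zero placement).
notch_coefficients <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + al)
  a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  list(b = b, a = a)
}

#' Normalize a signal to a fixed duration
#'
#' Records longer than the target are truncated to their last
#' `target_s` seconds; shorter records are zero-padded at the tail, so the
#' informative segment stays aligned to the start. The operation is
#' idempotent.
#'
#' @param signal Leads x samples matrix.
#' @param fs Sampling rate in Hz.
#' @param target_s Target duration in seconds (default 30, giving 15000
#'   samples at 500 Hz).
#' @return Leads x `round(target_s * fs)` matrix.
#' @export
fix_length <- function(signal, fs, target_s = 30) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  target <- as.integer(round(target_s * fs))
  L <- ncol(signal)
  if (L >= target) {
    signal[, (L - target + 1L):L, drop = FALSE]
  } else {
    cbind(signal, matrix(0, nrow = nrow(signal), ncol = target - L))
  }
}

#' Preprocess a record into the 1D model input
#'
#' Composition of [denoise()] and [fix_length()], producing the
#' one-dimensional branch input (12 x 15000 at the default 500 Hz / 30 s).
#' The notch frequency defaults by source database: 60 Hz for Georgia
#' records, 50 Hz otherwise.
#'
#' @param rec An [ecg_record].
#' @param powerline_hz Notch frequency; `NULL` selects it from the record's
#'   source database.
#' @param target_s Target duration in seconds.
#' @param standardize If `TRUE`, each lead is centred and scaled to unit
#'   variance after denoising (off by default; constant leads are left
#'   centred only).
#' @param ... Further arguments passed to [denoise()].
#' @return An `ecg_input1d`: leads x samples matrix with attribute
#'   `record_id`.
#' @export
preprocess_record <- function(rec, powerline_hz = NULL, target_s = 30,
                              standardize = FALSE, ...) {
  stopifnot(inherits(rec, "ecg_record"))
  if (is.null(powerline_hz))
    powerline_hz <- if (rec$source_db == "Georgia") 60 else 50
  x <- denoise(rec$signal, rec$fs, powerline_hz, ...)
  if (standardize) {
    mu <- rowMeans(x)
    sd <- apply(x, 1L, stats::sd)
    sd[sd == 0] <- 1
    x <- (x - mu) / sd
  }
  x <- fix_length(x, rec$fs, target_s)
  structure(x, record_id = rec$record_id, fs = rec$fs, class = "ecg_input1d")
}

#' @export
print.ecg_input1d <- function(x, ...) {
  cat(sprintf("<ecg_input1d %s> %d x %d\n", attr(x, "record_id"),
              nrow(x), ncol(x)))
  invisible(x)
}
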