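#' Hanning window
#'
#' Periodic raised-cosine taper `0.5 - 0.5 cos(2 pi n / N)`, `n = 0..N-1`
#' (the DFT-periodic convention used for spectrogram frames).
#'
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @export
hanning_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Short-time Fourier transform magnitude
#'
#' Splits a single lead into frames of `window_len` samples every `hop`
#' samples, applies a Hanning window, and returns one-sided DFT magnitudes:
#' frame t, bin k holds `|sum_n x[t hop + n] w[n] exp(-2 pi i k n / W)|`.
#'
#' @param lead Numeric vector (one lead).
#' @param window_len Window length in samples (default 256).
#' @param hop Frame advance in samples (default `window_len / 2`, i.e. 50%
#'   overlap).
#' @param fs Sampling rate, stored for bin spacing metadata.
#' @return Object of class `spectrogram`: frames x bins matrix of
#'   non-negative magnitudes with attributes `hop`, `window_len` and
#'   `bin_hz` (bin spacing `fs / window_len`).
#' @export
stft_magnitude <- function(lead, window_len = 256L, hop = window_len %/% 2L,
                           fs = 500) {
  lead <- as.numeric(lead)
  n <- length(lead)
  window_len <- as.integer(window_len); hop <- as.integer(hop)
  if (window_len > n)
    stopf("window length (%d) exceeds signal length (%d)", window_len, n)
  if (hop < 1L || hop > window_len)
    stopf("hop must lie in [1, window_len]")
  n_frames <- (n - window_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(lead[outer(seq_len(window_len), starts, "+")],
                   nrow = window_len)
  frames <- frames * hanning_window(window_len)
  spec <- stats::mvfft(frames)                   # window_len x n_frames
  n_bins <- window_len %/% 2L + 1L
  mag <- t(Mod(spec[seq_len(n_bins), , drop = FALSE]))
  structure(mag, hop = hop, window_len = window_len,
            bin_hz = fs / window_len, class = "spectrogram")
}

# Bilinear image resize; corners of the source grid map to corners of the
# target grid. Degenerate 1-row/column sources are replicated.
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  src_r <- if (h == 1L) rep(1, out_h) else (seq_len(out_h) - 1L) * (h - 1L) / (out_h - 1L) + 1
  src_c <- if (w == 1L) rep(1, out_w) else (seq_len(out_w) - 1L) * (w - 1L) / (out_w - 1L) + 1
  r0 <- pmin(floor(src_r), h - 1L); r0[h == 1L] <- 1L
  c0 <- pmin(floor(src_c), w - 1L); c0[w == 1L] <- 1L
  fr <- src_r - r0; fc <- src_c - c0
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  a <- img[r0, c0, drop = FALSE]; b <- img[r1, c0, drop = FALSE]
  cc <- img[r0, c1, drop = FALSE]; d <- img[r1, c1, drop = FALSE]
  top <- a * (1 - fr) + b * fr
  bot <- cc * (1 - fr) + d * fr
  top * rep(1 - fc, each = out_h) + bot * rep(fc, each = out_h)
}

#' Convert a 1D input into the stacked time-frequency model input
#'
#' Per lead: STFT magnitude (Hanning window), `log(1 + magnitude)`
#' compression, per-map min-max scaling to \[0,1\], bilinear resize to
#' `size x size`; the 12 maps are stacked in lead order. Row 1 of each map is
#' the lowest frequency, column 1 the earliest frame. A constant (e.g.
#' all-zero) map is mapped to all zeros rather than dividing by a zero range.
#'
#' @param x An `ecg_input1d` (leads x samples matrix) from
#'   [preprocess_record()], or any numeric leads x samples matrix.
#' @param window_len,hop STFT parameters (defaults 256 and 128).
#' @param size Output resolution (default 224).
#' @param fs Sampling rate (taken from `x`'s attribute when present).
#' @return An `ecg_tfmap`: array `leads x size x size` with values in
#'   \[0,1\] and attribute `record_id`.
#' @export
to_tfmap <- function(x, window_len = 256L, hop = window_len %/% 2L,
                     size = 224L, fs = NULL) {
  if (is.null(fs)) fs <- attr(x, "fs") %||% 500
  xm <- unclass(x)
  n_lead <- nrow(xm)
  out <- array(0, dim = c(n_lead, size, size))
  for (l in seq_len(n_lead)) {
    mag <- stft_magnitude(xm[l, ], window_len, hop, fs)
    m <- log1p(t(unclass(mag)))                  # bins x frames: freq rows
    rng <- range(m)
    m <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
    out[l, , ] <- bilinear_resize(m, size, size)
  }
  out <- pmin(pmax(out, 0), 1)
  structure(out, record_id = attr(x, "record_id"), class = "ecg_tfmap")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ecg_tfmap <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ecg_tfmap %s> %d x %d x %d in [%.3f, %.3f]\n",
              attr(x, "record_id") %||% "?", d[1], d[2], d[3],
              min(x), max(x)))
  invisible(x)
}
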