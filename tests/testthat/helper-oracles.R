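# Independent oracles shared across the suite. These deliberately avoid the
# package's own signal-path code: the peak detector works on slope energy,
# the DFT oracle is a naive O(n^2) sum, the feature extractor is hand-crafted.

# R-peak detector: moving average of the summed squared amplitudes across
# leads (QRS complexes dominate the multi-lead energy), threshold +
# refractory, peak = energy argmax of each supra-threshold segment.
detect_peaks <- function(signal, fs, thr_frac = 0.35, refractory = 0.22) {
  e <- colSums(signal^2)
  w <- max(3L, round(0.06 * fs))
  e <- stats::filter(e, rep(1 / w, w), sides = 2)
  e[is.na(e)] <- 0
  cand <- which(e > thr_frac * max(e))
  if (!length(cand)) return(numeric(0))
  seg_end <- cand[c(which(diff(cand) > 1), length(cand))]
  seg_start <- cand[c(1, which(diff(cand) > 1) + 1)]
  peaks <- vapply(seq_along(seg_start), function(i) {
    seg <- seg_start[i]:seg_end[i]
    seg[which.max(e[seg])]
  }, 0L)
  peaks <- sort(peaks)
  keep <- integer(0); last <- -Inf
  for (p in peaks) {
    if ((p - last) / fs >= refractory) {
      keep <- c(keep, p); last <- p
    } else if (e[p] > e[last]) {
      keep[length(keep)] <- p; last <- p
    }
  }
  keep / fs
}

# Naive windowed DFT magnitude of frame `fr` (1-based), one-sided bins.
naive_stft_frame <- function(lead, window_len, hop, fr) {
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window_len) - 1) / window_len)
  seg <- lead[(fr - 1) * hop + seq_len(window_len)] * w
  n <- window_len
  vapply(0:(n / 2), function(k)
    Mod(sum(seg * exp(-2i * pi * k * (seq_len(n) - 1) / n))), 0)
}

# Hand-crafted rhythm/morphology features (rate, RR regularity, QRS width,
# P-wave/PR measurements, precordial polarities) used for the
# class-separability calibration.
extract_features <- function(rec) {
  x <- denoise(rec$signal, rec$fs, 50)
  fs <- rec$fs
  pk <- detect_peaks(x, fs)
  if (length(pk) < 3) return(rep(0, 14))
  rr <- diff(pk)
  ii <- x[2, ]
  qw <- vapply(pk, function(p) {
    i0 <- max(1, round((p - 0.12) * fs)); i1 <- min(ncol(x), round((p + 0.12) * fs))
    seg <- abs(ii[i0:i1])
    sum(seg > 0.25 * max(seg)) / fs
  }, 0)
  pamp <- vapply(pk, function(p) {
    # narrow pre-R window: catches the P wave, avoids the previous T wave
    i0 <- max(1, round((p - 0.22) * fs)); i1 <- max(1, round((p - 0.08) * fs))
    if (i1 <= i0) 0 else max(ii[i0:i1])
  }, 0)
  pr <- vapply(pk, function(p) {
    i0 <- max(1, round((p - 0.40) * fs)); i1 <- max(1, round((p - 0.06) * fs))
    if (i1 <= i0) 0 else p - (i0 + which.max(ii[i0:i1]) - 1) / fs
  }, 0)
  pol <- function(lead) stats::median(vapply(pk, function(p) {
    i0 <- max(1, round((p - 0.06) * fs)); i1 <- min(ncol(x), round((p + 0.06) * fs))
    s <- lead[i0:i1]
    s[which.max(abs(s))]
  }, 0))
  c(hr = 60 / mean(rr), cv = stats::sd(rr) / mean(rr),
    early = mean(rr < 0.8 * stats::median(rr)),
    qw_med = stats::median(qw), qw_max = max(qw), qw_sd = stats::sd(qw),
    pamp_med = stats::median(pamp), pamp_min = min(pamp),
    pr_med = stats::median(pr), pr_q90 = unname(stats::quantile(pr, 0.9)),
    v1 = pol(x[7, ]), v6 = pol(x[12, ]),
    ramp = stats::median(abs(ii[pmin(ncol(x), round(pk * fs) + 1)])),
    rrmin = min(rr) / stats::median(rr))
}

first_label <- function(rec) names(rec$labels)[rec$labels == 1][1]

clean_noise <- function() synth_noise_config(0, 0, 50, 0)

# Copy every weight of `dst` from the identically named weight of `src`.
copy_shared_weights <- function(dst, src) {
  fsrc <- ecmam:::flatten_params(src$params)
  for (nm in names(ecmam:::flatten_params(dst$params))) {
    stopifnot(nm %in% names(fsrc))
    dst$params[[ecmam:::param_path(nm)]] <- fsrc[[nm]]
  }
  dst
}

# Small configuration used where only mechanics (not capacity) matter.
micro_config <- function(...) {
  args <- utils::modifyList(
    list(profile = "tiny", widths = c(2L, 2L, 2L, 2L), input_len = 64L,
         map_size = 16L, fusion_hidden = 8L, stem1d_kernel = 7L,
         k_spatial = 3L, dropout = 0),
    list(...))
  do.call(model_config, args)
}

num_grad <- function(f, z, h = 1e-6) {
  g <- array(0, if (is.null(dim(z))) length(z) else dim(z))
  for (i in seq_along(z)) {
    zp <- z; zp[i] <- z[i] + h
    zm <- z; zm[i] <- z[i] - h
    g[i] <- (f(zp) - f(zm)) / (2 * h)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}
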