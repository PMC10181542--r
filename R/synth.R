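# Synthetic 12-lead ECG generator. A beat is a sum of Gaussian waves (P, Q,
# R, S, T) on the time axis; three source channels (P wave, QRS complex,
# T wave; plus a fourth for ectopic QRS morphology) are projected to the 12
# leads through fixed direction-coefficient vectors that encode the
# class-conditional polarity patterns (aVR inversion, V1/V6 bundle-branch
# signatures). These coefficient tables are the generator's ground truth.

lead_coefficients <- function(variant = c("normal", "lbbb", "rbbb", "pvc")) {
  variant <- match.arg(variant)
  p <- c(0.8, 1.0, 0.3, -0.9, 0.2, 0.8, 0.2, 0.3, 0.3, 0.4, 0.4, 0.4)
  qrs <- switch(variant,
    normal = c(0.8, 1.0, 0.4, -0.9, 0.3, 0.7, -0.4, -0.2, 0.2, 0.8, 1.0, 0.9),
    lbbb   = c(1.0, 0.9, 0.2, -0.9, 0.5, 0.6, -1.0, -0.9, -0.4, 0.4, 1.1, 1.2),
    rbbb   = c(0.6, 0.8, 0.4, -0.8, 0.2, 0.6, 1.0, 0.7, 0.4, 0.3, 0.4, 0.3),
    pvc    = c(-0.6, -0.9, -0.4, 0.8, -0.2, -0.7, 0.9, 0.8, 0.5, -0.5, -0.9, -0.8))
  tw <- if (variant %in% c("lbbb", "rbbb", "pvc")) -0.45 * qrs else 0.5 * qrs
  m <- cbind(P = p, QRS = qrs, T = tw)
  rownames(m) <- standard_leads()
  m
}

# Gaussian wave components of one beat, as offsets (s) from the R peak.
# The R width is qrs_width/3 so the duration of the complex above 25% of
# its peak tracks the programmed QRS duration. Wide (>=120 ms) complexes are
# broad and near-monophasic (bundle-branch / ventricular morphology): their
# opposing Q/S lobes are scaled down.
beat_template <- function(qrs_width = 0.09, pr = 0.16, p_present = TRUE,
                          r_amp = 1.1) {
  half <- qrs_width / 2
  qs <- if (qrs_width >= 0.12) 0.35 else 1
  comps <- list(
    Q = list(src = "QRS", amp = -0.12 * r_amp * qs, center = -half * 0.7,
             width = qrs_width / 7),
    R = list(src = "QRS", amp = r_amp, center = 0, width = qrs_width / 3),
    S = list(src = "QRS", amp = -0.25 * r_amp * qs, center = half * 0.7,
             width = qrs_width / 7),
    T = list(src = "T", amp = 0.30, center = 0.28 + qrs_width, width = 0.06))
  if (p_present)
    comps$P <- list(src = "P", amp = 0.15, center = -pr, width = 0.022)
  comps
}

#' Noise configuration for the synthetic generator
#'
#' @param baseline Baseline-wander amplitude in mV (sinusoid at a random
#'   0.15-0.3 Hz frequency).
#' @param powerline Mains-interference amplitude in mV.
#' @param powerline_hz Mains frequency in Hz.
#' @param emg White-noise (EMG) standard deviation in mV.
#' @return List of noise settings.
#' @export
synth_noise_config <- function(baseline = 0.15, powerline = 0.04,
                               powerline_hz = 50, emg = 0.02) {
  list(baseline = baseline, powerline = powerline,
       powerline_hz = powerline_hz, emg = emg)
}

# Class-conditional rhythm parameters, drawn per record (RNG already seeded).
rhythm_spec <- function(label) {
  switch(label,
    SNR   = list(hr = stats::runif(1, 62, 98), rr_cv = 0.02, pr = 0.16,
                 qrs = stats::runif(1, 0.08, 0.10), p = TRUE,
                 qrs_variant = "normal", ectopic = NULL),
    SB    = list(hr = stats::runif(1, 40, 57), rr_cv = 0.02, pr = 0.16,
                 qrs = stats::runif(1, 0.08, 0.10), p = TRUE,
                 qrs_variant = "normal", ectopic = NULL),
    STach = list(hr = stats::runif(1, 104, 150), rr_cv = 0.02, pr = 0.14,
                 qrs = stats::runif(1, 0.08, 0.10), p = TRUE,
                 qrs_variant = "normal", ectopic = NULL),
    AF    = list(hr = stats::runif(1, 70, 130), rr_cv = 0.28, pr = 0.16,
                 qrs = stats::runif(1, 0.08, 0.10), p = FALSE,
                 qrs_variant = "normal", ectopic = NULL),
    IAVB  = list(hr = stats::runif(1, 55, 90), rr_cv = 0.02,
                 pr = stats::runif(1, 0.24, 0.32),
                 qrs = stats::runif(1, 0.08, 0.10), p = TRUE,
                 qrs_variant = "normal", ectopic = NULL),
    LBBB  = list(hr = stats::runif(1, 60, 95), rr_cv = 0.02, pr = 0.17,
                 qrs = stats::runif(1, 0.14, 0.17), p = TRUE,
                 qrs_variant = "lbbb", ectopic = NULL),
    RBBB  = list(hr = stats::runif(1, 60, 95), rr_cv = 0.02, pr = 0.17,
                 qrs = stats::runif(1, 0.14, 0.17), p = TRUE,
                 qrs_variant = "rbbb", ectopic = NULL),
    PAC   = list(hr = stats::runif(1, 65, 95), rr_cv = 0.02, pr = 0.16,
                 qrs = stats::runif(1, 0.08, 0.10), p = TRUE,
                 qrs_variant = "normal",
                 ectopic = list(type = "PAC", rate = 0.22)),
    PVC   = list(hr = stats::runif(1, 65, 95), rr_cv = 0.02, pr = 0.16,
                 qrs = stats::runif(1, 0.08, 0.10), p = TRUE,
                 qrs_variant = "normal",
                 ectopic = list(type = "PVC", rate = 0.22)),
    stopf("unknown class label '%s'", label))
}

# Beat schedule: times (s), each flagged normal/ectopic. Ectopics arrive
# early (coupling 0.55 RR) and are followed by a compensatory pause.
beat_schedule <- function(spec, duration) {
  rr0 <- 60 / spec$hr
  times <- numeric(0); types <- character(0)
  t <- stats::runif(1, 0.2, min(0.5, rr0))
  pending_pause <- FALSE
  while (t < duration - 0.3) {
    times <- c(times, t); types <- c(types, "normal")
    rr <- if (spec$rr_cv > 0.1)
      rr0 * exp(stats::rnorm(1, -spec$rr_cv^2 / 2, spec$rr_cv))
    else rr0 * (1 + stats::rnorm(1, 0, spec$rr_cv))
    rr <- max(rr, 0.25)
    if (!is.null(spec$ectopic) && stats::runif(1) < spec$ectopic$rate) {
      te <- t + 0.55 * rr0
      if (te < duration - 0.3) {
        times <- c(times, te); types <- c(types, "ectopic")
      }
      t <- t + 1.55 * rr0                    # compensatory pause
    } else {
      t <- t + rr
    }
  }
  list(times = times, types = types)
}

add_wave <- function(src_row, tvec, fs, center, amp, width) {
  lo <- max(1L, floor((center - 5 * width) * fs) + 1L)
  hi <- min(length(src_row), ceiling((center + 5 * width) * fs) + 1L)
  if (lo > hi) return(src_row)
  seg <- tvec[lo:hi]
  src_row[lo:hi] <- src_row[lo:hi] + amp * exp(-(seg - center)^2 / (2 * width^2))
  src_row
}

#' Generate one labelled synthetic 12-lead ECG record
#'
#' Deterministic given `(label, seed)`. Class rules: SNR 60-100 bpm regular
#' with P waves; SB below 60 bpm; STach above 100 bpm; AF irregular RR
#' (coefficient of variation above 0.15) with absent P waves; IAVB PR
#' interval above 200 ms; LBBB/RBBB QRS above 120 ms with opposite V1/V6
#' polarity; PAC/PVC sinus rhythm with early inserted beats (narrow with P
#' for PAC, wide without P and discordant polarity for PVC). Noise adds a
#' baseline-wander sinusoid, mains interference and white EMG noise.
#'
#' @param label Class label from [class_vocabulary()]; a vector of two
#'   labels (e.g. `c("AF", "PAC")`) generates the first rhythm with the
#'   second class's ectopic beats and both labels set.
#' @param duration Record length in seconds (6-60).
#' @param fs Sampling rate in Hz.
#' @param noise_cfg From [synth_noise_config()]; set amplitudes to 0 for a
#'   clean record.
#' @param seed Integer seed.
#' @return An [ecg_record] (source `"SYNTH"`) with attributes `beat_times`
#'   (programmed R-peak times, s), `beat_types` and `rhythm` (the drawn
#'   parameters).
#' @export
synth_record <- function(label, duration = 10, fs = 500,
                         noise_cfg = synth_noise_config(), seed = 1L) {
  labels <- match.arg(label, class_vocabulary(), several.ok = TRUE)
  if (duration < 6 || duration > 60)
    stopf("duration must lie in [6, 60] s, got %g", duration)
  with_seed(seed, {
    spec <- rhythm_spec(labels[1L])
    if (length(labels) > 1L && labels[2L] %in% c("PAC", "PVC"))
      spec$ectopic <- list(type = labels[2L], rate = 0.22)
    n <- as.integer(round(duration * fs))
    tvec <- (seq_len(n) - 1L) / fs
    sched <- beat_schedule(spec, duration)
    src <- matrix(0, nrow = 4L, ncol = n,
                  dimnames = list(c("P", "QRS", "T", "QRSect"), NULL))
    tmpl_n <- beat_template(spec$qrs, spec$pr, spec$p, r_amp = 1.1)
    ect_type <- if (!is.null(spec$ectopic)) spec$ectopic$type else NULL
    tmpl_e <- if (identical(ect_type, "PVC"))
      beat_template(stats::runif(1, 0.15, 0.19), pr = 0, p_present = FALSE,
                    r_amp = 1.4)
    else if (identical(ect_type, "PAC"))
      beat_template(spec$qrs, pr = 0.12, p_present = TRUE, r_amp = 1.0)
    else NULL
    for (i in seq_along(sched$times)) {
      ect <- sched$types[i] == "ectopic"
      tmpl <- if (ect) tmpl_e else tmpl_n
      for (cm in tmpl) {
        row <- if (ect && identical(ect_type, "PVC") && cm$src == "QRS")
          "QRSect" else cm$src
        src[row, ] <- add_wave(src[row, ], tvec, fs,
                               sched$times[i] + cm$center, cm$amp, cm$width)
      }
    }
    co <- lead_coefficients(spec$qrs_variant)
    co_e <- lead_coefficients("pvc")[, "QRS"]
    sig <- co %*% src[c("P", "QRS", "T"), ] + co_e %o% src["QRSect", ]
    if (noise_cfg$baseline > 0) {
      bf <- stats::runif(1, 0.15, 0.3)
      ph <- stats::runif(12, 0, 2 * pi)
      amp <- noise_cfg$baseline * stats::runif(12, 0.5, 1)
      sig <- sig + amp * sin(outer(ph, 2 * pi * bf * tvec, "+"))
    }
    if (noise_cfg$powerline > 0)
      sig <- sig + noise_cfg$powerline *
        sin(outer(stats::runif(12, 0, 2 * pi),
                  2 * pi * noise_cfg$powerline_hz * tvec, "+"))
    if (noise_cfg$emg > 0)
      sig <- sig + matrix(stats::rnorm(12 * n, 0, noise_cfg$emg), 12L, n)
    lab <- stats::setNames(integer(9L), class_vocabulary())
    lab[labels] <- 1L
    rec <- ecg_record(sprintf("%s-%08d", paste(labels, collapse = "+"),
                              as.integer(seed) %% 1e8L),
                      sig, fs, lab, "SYNTH")
    attr(rec, "beat_times") <- sched$times
    attr(rec, "beat_types") <- sched$types
    attr(rec, "rhythm") <- spec
    rec
  })
}

#' Generate a labelled synthetic dataset
#'
#' `n_per_class` records per rhythm class, durations drawn uniformly from
#' `duration` (spec the record-length range of the source databases, 6-60 s,
#' by default). Reproducible by seed.
#'
#' @param n_per_class Records per class.
#' @param duration Length-2 range of durations in seconds (or a single
#'   value).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param noise_cfg From [synth_noise_config()].
#' @param multi_label_rate Fraction of PAC records generated as AF base
#'   rhythm with atrial ectopics and labelled AF+PAC, exercising multi-label
#'   paths (default 0).
#' @return List with `records` and `summary` (the [summarize_dataset()]
#'   table).
#' @export
synth_dataset <- function(n_per_class, duration = c(6, 60), fs = 500,
                          seed = 1L, noise_cfg = synth_noise_config(),
                          multi_label_rate = 0) {
  stopifnot(n_per_class >= 1)
  duration <- rep(duration, length.out = 2L)
  vocab <- class_vocabulary()
  plan <- with_seed(seed, {
    data.frame(
      label = rep(vocab, each = n_per_class),
      dur = stats::runif(9L * n_per_class, duration[1], duration[2]),
      sub_seed = sample.int(.Machine$integer.max - 1L, 9L * n_per_class),
      multi = stats::runif(9L * n_per_class) < multi_label_rate)
  })
  records <- lapply(seq_len(nrow(plan)), function(i) {
    lab <- plan$label[i]
    if (lab == "PAC" && plan$multi[i]) lab <- c("AF", "PAC")
    synth_record(lab, plan$dur[i], fs, noise_cfg, plan$sub_seed[i])
  })
  for (i in seq_along(records))
    records[[i]]$record_id <- sprintf("S%05d-%s", i, plan$label[i])
  list(records = records, summary = summarize_dataset(records))
}
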