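test_that("rate classes obey their heart-rate rules by an independent count", {
  sb <- synth_record("SB", duration = 12, fs = 250,
                     noise_cfg = clean_noise(), seed = 3)
  st <- synth_record("STach", duration = 12, fs = 250,
                     noise_cfg = clean_noise(), seed = 3)
  snr <- synth_record("SNR", duration = 12, fs = 250,
                      noise_cfg = clean_noise(), seed = 3)
  rate <- function(rec) {
    pk <- detect_peaks(rec$signal, rec$fs)
    60 * (length(pk) - 1) / (max(pk) - min(pk))
  }
  expect_lt(rate(sb), 60)
  expect_gt(rate(st), 100)
  r <- rate(snr)
  expect_true(r > 60 && r < 100)
})

test_that("AF is irregular without P waves while sinus rhythm is regular", {
  rr_cv <- function(rec) {
    rr <- diff(detect_peaks(rec$signal, rec$fs))
    stats::sd(rr) / mean(rr)
  }
  af <- synth_record("AF", duration = 20, fs = 250,
                     noise_cfg = clean_noise(), seed = 5)
  snr <- synth_record("SNR", duration = 20, fs = 250,
                      noise_cfg = clean_noise(), seed = 5)
  expect_gt(rr_cv(af), 0.15)
  expect_lt(rr_cv(snr), 0.05)
  # P-wave amplitude just before the R peak: present for SNR, absent for AF
  p_of <- function(rec) extract_features(rec)[["pamp_med"]]
  expect_gt(p_of(snr), 0.01)
  expect_lt(p_of(af), 0.01)
})

test_that("conduction classes obey PR and QRS-width rules with V1/V6 polarity", {
  iavb <- synth_record("IAVB", duration = 12, fs = 250,
                       noise_cfg = clean_noise(), seed = 8)
  snr <- synth_record("SNR", duration = 12, fs = 250,
                      noise_cfg = clean_noise(), seed = 8)
  expect_gt(extract_features(iavb)[["pr_med"]], 0.2)
  expect_lt(extract_features(snr)[["pr_med"]], 0.2)
  lb <- synth_record("LBBB", duration = 12, fs = 250,
                     noise_cfg = clean_noise(), seed = 9)
  rb <- synth_record("RBBB", duration = 12, fs = 250,
                     noise_cfg = clean_noise(), seed = 9)
  flb <- extract_features(lb); frb <- extract_features(rb)
  fsn <- extract_features(snr)
  expect_gt(flb[["qw_med"]], 0.12)
  expect_gt(frb[["qw_med"]], 0.12)
  expect_lt(fsn[["qw_med"]], 0.12)
  # bundle-branch V1 polarity: negative for LBBB, positive for RBBB
  expect_lt(flb[["v1"]], 0)
  expect_gt(frb[["v1"]], 0)
  expect_gt(flb[["v6"]], 0)
})

test_that("ectopic classes insert early beats of the right morphology", {
  pac <- synth_record("PAC", duration = 20, fs = 250,
                      noise_cfg = clean_noise(), seed = 10)
  pvc <- synth_record("PVC", duration = 20, fs = 250,
                      noise_cfg = clean_noise(), seed = 10)
  expect_true("ectopic" %in% attr(pac, "beat_types"))
  expect_true("ectopic" %in% attr(pvc, "beat_types"))
  # early beats shorten the minimum RR well below the median
  for (rec in list(pac, pvc)) {
    rr <- diff(detect_peaks(rec$signal, rec$fs, refractory = 0.2))
    expect_lt(min(rr) / stats::median(rr), 0.8)
  }
  # PVC ectopics are wide: max beat width exceeds the PAC one
  expect_gt(extract_features(pvc)[["qw_max"]],
            extract_features(pac)[["qw_max"]])
})

test_that("generation is bit-identical under a repeated seed", {
  a <- synth_record("AF", duration = 10, fs = 250, seed = 42)
  b <- synth_record("AF", duration = 10, fs = 250, seed = 42)
  expect_identical(a$signal, b$signal)
  expect_identical(attr(a, "beat_times"), attr(b, "beat_times"))
  c_ <- synth_record("AF", duration = 10, fs = 250, seed = 43)
  expect_false(identical(a$signal, c_$signal))
  expect_error(synth_record("AF", duration = 3), "6, 60")
  expect_error(synth_record("XYZ", duration = 10))
})

test_that("the dataset generator hits its count and duration contracts", {
  ds <- synth_dataset(5, duration = c(6, 60), fs = 125, seed = 2)
  expect_length(ds$records, 45L)
  expect_true(all(ds$summary$counts[, "Total"] == 5L))
  durs <- vapply(ds$records, function(r) ncol(r$signal) / r$fs, 0)
  expect_true(all(durs >= 6 & durs <= 60))
  # WFDB round trip preserves the summary table
  dir <- withr::local_tempdir()
  for (r in ds$records) save_record(r, dir)
  back <- assemble_dataset(dir)
  expect_equal(summarize_dataset(back)$counts[, "Total"],
               ds$summary$counts[, "Total"])
  # multi-label option produces AF+PAC records
  dm <- synth_dataset(4, duration = c(8, 8), fs = 125, seed = 3,
                      multi_label_rate = 1)
  nlab <- vapply(dm$records, function(r) sum(r$labels), 0L)
  expect_true(any(nlab == 2L))
  s <- summarize_dataset(dm$records)
  expect_gt(sum(s$counts[, "Total"]), s$n_records)
})

test_that("programmed beat times are recovered by the independent detector", {
  for (lab in c("SNR", "SB", "STach", "AF", "IAVB", "LBBB", "RBBB")) {
    rec <- synth_record(lab, duration = 12, fs = 250,
                        noise_cfg = clean_noise(), seed = 21)
    bt <- attr(rec, "beat_times")
    pk <- detect_peaks(rec$signal, rec$fs)
    expect_equal(length(pk), length(bt))
    err <- vapply(bt, function(b) min(abs(pk - b)), 0)
    expect_lt(max(err), 0.020)
  }
  # wide ectopic beats localize more loosely but are all found
  for (lab in c("PAC", "PVC")) {
    rec <- synth_record(lab, duration = 12, fs = 250,
                        noise_cfg = clean_noise(), seed = 21)
    bt <- attr(rec, "beat_times")
    pk <- detect_peaks(rec$signal, rec$fs, refractory = 0.2)
    expect_equal(length(pk), length(bt))
    err <- vapply(bt, function(b) min(abs(pk - b)), 0)
    expect_lt(max(err), 0.050)
  }
})

test_that("hand-crafted features separate the nine classes (calibration)", {
  skip_if_not_installed("randomForest")
  # default generator settings: 500 Hz, 6-60 s, noise on
  ds <- synth_dataset(15, seed = 77)
  X <- t(vapply(ds$records, extract_features, numeric(14)))
  y <- factor(vapply(ds$records, first_label, ""))
  idx <- unlist(lapply(split(seq_along(y), y), function(i) i[1:10]))
  set.seed(1)
  rf <- randomForest::randomForest(X[idx, ], y[idx], ntree = 300)
  pred <- predict(rf, X[-idx, ])
  f1 <- vapply(levels(y), function(cl) {
    tp <- sum(pred == cl & y[-idx] == cl)
    fp <- sum(pred == cl & y[-idx] != cl)
    fn <- sum(pred != cl & y[-idx] == cl)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, 0)
  expect_gt(mean(f1), 0.9)
})
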