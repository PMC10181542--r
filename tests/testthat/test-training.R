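test_that("class weights follow the inverse-log rule", {
  expect_equal(class_weights(c(exp(1), exp(1)))$w, c(1, 1))   # 1/ln e
  w <- class_weights(c(10, 100))$w
  expect_equal(w, c(1 / log(10), 1 / log(100)), tolerance = 1e-12)
  expect_equal(round(w, 5), c(0.43429, 0.21715))
  expect_equal(w[1] / w[2], 2, tolerance = 1e-12)
  expect_error(class_weights(c(1, 10)), ">= 2")
  expect_error(class_weights(c(NA, 10)), "finite")
  # published-table-sized counts: more positives, strictly smaller weight
  counts <- c(1894, 1590, 496, 2496, 1370, 1280, 1722, 1560, 2663)
  w9 <- class_weights(counts)$w
  for (i in 1:8) for (j in (i + 1):9)
    expect_equal(sign(w9[i] - w9[j]), sign(counts[j] - counts[i]))
  # sorted counts ascending give weights descending
  ws <- class_weights(sort(counts))$w
  expect_true(all(diff(ws) < 0))
})

test_that("weighted cross-entropy matches closed forms and is linear in w", {
  # single class, w = 1, y = 1, yhat = 0.5 -> ln 2
  expect_equal(weighted_bce(0.5, 1, 1), log(2), tolerance = 1e-12)
  # vertex: correct confident prediction gives (numerically) zero loss
  y <- c(1, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_lt(weighted_bce(y, y, rep(1, 9)), 9 * 1.5 * 1e-6)
  # doubling one class weight doubles that class's contribution
  set.seed(1)
  yhat <- runif(9, 0.1, 0.9); yy <- rbinom(9, 1, 0.5)
  w <- runif(9, 0.5, 2)
  w2 <- w; w2[3] <- 2 * w[3]
  base <- weighted_bce(yhat, yy, w)
  only3 <- weighted_bce(yhat, yy, w2) - base
  w0 <- w; w0[3] <- 0
  expect_equal(only3, base - weighted_bce(yhat, yy, w0), tolerance = 1e-10)
})

test_that("loss is non-negative with the vertex minimum under fuzzing", {
  set.seed(2)
  losses <- replicate(10000, weighted_bce(runif(9), rbinom(9, 1, 0.5)))
  expect_true(all(losses >= 0))
  # loss at the true vertex never exceeds loss elsewhere
  yy <- rbinom(9, 1, 0.5)
  expect_lt(weighted_bce(yy, yy), weighted_bce(runif(9, 0.2, 0.8), yy))
})

test_that("analytic loss gradient matches central finite differences", {
  set.seed(3)
  for (rep in 1:5) {
    yhat <- runif(9, 0.05, 0.95)
    yy <- rbinom(9, 1, 0.5)
    w <- runif(9, 0.3, 1.5)
    g <- weighted_bce_grad(yhat, yy, w)
    g_num <- num_grad(function(z) weighted_bce(z, yy, w), yhat, h = 1e-7)
    expect_lt(max(abs(g - g_num)) / max(abs(g_num)), 1e-5)
  }
})

test_that("the learning rate halves after every tenth epoch", {
  cfg <- train_config()
  expect_equal(lr_at(1, cfg), 0.001)
  expect_equal(lr_at(10, cfg), 0.001)
  expect_equal(lr_at(11, cfg) / lr_at(1, cfg), 0.5)
  expect_equal(lr_at(21, cfg), 0.001 * 0.25)
  expect_error(lr_at(0, cfg))
  expect_error(train_config(lr = -1))
  expect_error(train_config(decay_factor = 1.5))
})

test_that("a learnable two-class toy reduces the training loss deterministically", {
  cfg <- micro_config()
  recs <- c(lapply(1:20, function(i)
    synth_record("SB", duration = 6, fs = cfg$fs, seed = 100 + i)),
    lapply(1:20, function(i)
      synth_record("STach", duration = 6, fs = cfg$fs, seed = 200 + i)))
  # 6 s at 125 Hz -> 750 samples; pad to the micro input by configuration
  cfg2 <- micro_config(input_len = 750L, target_s = 6, map_size = 16L,
                       stft_window = 64L, stft_hop = 32L)
  data <- prepare_model_inputs(recs, cfg2)
  model <- build_model("EC-MAM", cfg2, seed = 1)
  tcfg <- train_config(epochs = 5L, batch_size = 16L, seed = 1L)
  res <- train_fold(model, data, val_data = NULL, cfg = tcfg)
  expect_lt(tail(res$history$train_loss, 1), res$history$train_loss[1])
  # same seed twice: identical epoch-1 loss
  model_b <- build_model("EC-MAM", cfg2, seed = 1)
  res_b <- train_fold(model_b, data, val_data = NULL,
                      cfg = train_config(epochs = 1L, batch_size = 16L,
                                         seed = 1L))
  expect_equal(res_b$history$train_loss[1], res$history$train_loss[1],
               tolerance = 1e-12)
  expect_error(train_fold(model, list(y = matrix(0, 0, 9)), NULL, tcfg),
               "empty")
})
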