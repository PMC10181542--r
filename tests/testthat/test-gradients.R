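# Finite-difference checks of every backward pass. These pin the hand-derived
# gradients that the training loop depends on.

test_that("convolution gradients match central finite differences", {
  set.seed(1)
  x <- array(rnorm(10 * 3 * 2), c(10, 3, 2))
  W <- array(rnorm(3 * 3 * 4, sd = 0.5), c(3, 3, 4)); b <- rnorm(4)
  fw <- ecmam:::conv1d_fw(x, W, b, stride = 2L, pad = 1L)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- ecmam:::conv1d_bw(dy, fw$cache)
  expect_lt(max_rel_err(bw$dx, num_grad(function(z)
    sum(ecmam:::conv1d_fw(z, W, b, 2L, 1L)$y * dy), x)), 1e-6)
  expect_lt(max_rel_err(bw$dW, num_grad(function(z)
    sum(ecmam:::conv1d_fw(x, z, b, 2L, 1L)$y * dy), W)), 1e-6)
  expect_lt(max_rel_err(bw$db, num_grad(function(z)
    sum(ecmam:::conv1d_fw(x, W, z, 2L, 1L)$y * dy), b)), 1e-6)

  x2 <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  W2 <- array(rnorm(3 * 3 * 2 * 3, sd = 0.5), c(3, 3, 2, 3)); b2 <- rnorm(3)
  fw2 <- ecmam:::conv2d_fw(x2, W2, b2, stride = 2L, pad = 1L)
  dy2 <- array(rnorm(length(fw2$y)), dim(fw2$y))
  bw2 <- ecmam:::conv2d_bw(dy2, fw2$cache)
  expect_lt(max_rel_err(bw2$dx, num_grad(function(z)
    sum(ecmam:::conv2d_fw(z, W2, b2, 2L, 1L)$y * dy2), x2)), 1e-6)
  expect_lt(max_rel_err(bw2$dW, num_grad(function(z)
    sum(ecmam:::conv2d_fw(x2, z, b2, 2L, 1L)$y * dy2), W2)), 1e-6)
})

test_that("pooling and batch-norm gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(10 * 3 * 2), c(10, 3, 2))
  fp <- ecmam:::maxpool1d_fw(x, 3L, 2L, 1L)
  dyp <- array(rnorm(length(fp$y)), dim(fp$y))
  expect_lt(max_rel_err(ecmam:::maxpool1d_bw(dyp, fp$cache),
                        num_grad(function(z)
                          sum(ecmam:::maxpool1d_fw(z, 3L, 2L, 1L)$y * dyp),
                          x)), 1e-6)
  x2 <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  fp2 <- ecmam:::maxpool2d_fw(x2, 3L, 2L, 1L)
  dyp2 <- array(rnorm(length(fp2$y)), dim(fp2$y))
  expect_lt(max_rel_err(ecmam:::maxpool2d_bw(dyp2, fp2$cache),
                        num_grad(function(z)
                          sum(ecmam:::maxpool2d_fw(z, 3L, 2L, 1L)$y * dyp2),
                          x2)), 1e-6)
  p <- ecmam:::bn_init(3L)
  fb <- ecmam:::bn_fw(x, p, training = TRUE)
  dyb <- array(rnorm(length(fb$y)), dim(fb$y))
  bb <- ecmam:::bn_bw(dyb, fb$cache)
  pb <- ecmam:::bn_init(3L)
  expect_lt(max_rel_err(bb$dx, num_grad(function(z)
    sum(ecmam:::bn_fw(z, pb, training = TRUE)$y * dyb), x, h = 1e-5)), 1e-5)
})

test_that("attention-gate gradients match finite differences", {
  set.seed(3)
  x <- array(rnorm(10 * 3 * 2), c(10, 3, 2))
  pa <- ecmam:::att1d_init(3L, 2L)
  fa <- ecmam:::ca1d_fw(x, pa)
  dya <- array(rnorm(length(fa$y)), dim(fa$y))
  ba <- ecmam:::ca1d_bw(dya, fa$cache, pa)
  expect_lt(max_rel_err(ba$dx, num_grad(function(z)
    sum(ecmam:::ca1d_fw(z, pa)$y * dya), x)), 1e-6)
  expect_lt(max_rel_err(ba$dW2, num_grad(function(z) {
    pp <- pa; pp$W2 <- z
    sum(ecmam:::ca1d_fw(x, pp)$y * dya)
  }, pa$W2)), 1e-6)

  x2 <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  p2 <- ecmam:::att2d_init(2L, 2L, 3L)
  fh <- ecmam:::hca2d_fw(x2, p2)
  dyh <- array(rnorm(length(fh$y)), dim(fh$y))
  bh <- ecmam:::hca2d_bw(dyh, fh$cache, p2)
  expect_lt(max_rel_err(bh$dx, num_grad(function(z)
    sum(ecmam:::hca2d_fw(z, p2)$y * dyh), x2)), 1e-6)
  expect_lt(max_rel_err(bh$dW2, num_grad(function(z) {
    pp <- p2; pp$W2 <- z
    sum(ecmam:::hca2d_fw(x2, pp)$y * dyh)
  }, p2$W2)), 1e-6)

  fs_ <- ecmam:::hsa2d_fw(x2, p2)
  dys <- array(rnorm(length(fs_$y)), dim(fs_$y))
  bs <- ecmam:::hsa2d_bw(dys, fs_$cache, p2)
  expect_lt(max_rel_err(bs$dx, num_grad(function(z)
    sum(ecmam:::hsa2d_fw(z, p2)$y * dys), x2)), 1e-6)
  expect_lt(max_rel_err(bs$dconv_W, num_grad(function(z) {
    pp <- p2; pp$conv$W <- z
    sum(ecmam:::hsa2d_fw(x2, pp)$y * dys)
  }, p2$conv$W)), 1e-6)
})

test_that("whole-model gradients agree with finite differences", {
  set.seed(4)
  cfg <- micro_config()
  m <- build_model("EC-MAM", cfg, seed = 2)
  n <- 2L
  x1 <- array(rnorm(64 * 12 * n), c(64, 12, n))
  x2 <- array(runif(16 * 16 * 12 * n), c(16, 16, 12, n))
  y <- matrix(rbinom(n * 9, 1, 0.3), n, 9)
  lossfun <- function(model) {
    fwd <- model_forward(model, x1, x2, training = TRUE, keep_caches = TRUE)
    p <- pmin(pmax(fwd$probs, 1e-7), 1 - 1e-7)
    mean(rowSums(-(y * log(p) + (1 - y) * log(1 - p))))
  }
  fwd <- model_forward(m, x1, x2, training = TRUE, keep_caches = TRUE)
  dlog <- t(fwd$probs - y) / n
  G <- ecmam:::flatten_params(ecmam:::model_backward(m, fwd, dlog))
  sel <- sample(names(G), 10)
  h <- 1e-5
  for (nm in sel) {
    path <- ecmam:::param_path(nm)
    j <- sample(seq_along(G[[nm]]), 1)
    mp <- ecmam:::clone_model(m); mp$params[[path]][j] <- mp$params[[path]][j] + h
    mm <- ecmam:::clone_model(m); mm$params[[path]][j] <- mm$params[[path]][j] - h
    g_num <- (lossfun(mp) - lossfun(mm)) / (2 * h)
    expect_lt(abs(g_num - G[[nm]][j]) /
                max(1e-4, abs(g_num), abs(G[[nm]][j])), 1e-3)
  }
})
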