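# Brute-force single-sample oracles, written with explicit elementwise
# arithmetic, independent of the package's batched implementations.
sig_ <- function(z) 1 / (1 + exp(-z))

ca_oracle <- function(F_, p) {
  s <- vapply(seq_len(nrow(F_)), function(c) mean(F_[c, ]), 0)
  a1 <- pmax(as.numeric(p$W1 %*% s + p$b1), 0)
  g <- sig_(as.numeric(p$W2 %*% a1 + p$b2))
  out <- F_
  for (c in seq_len(nrow(F_))) out[c, ] <- g[c] * F_[c, ]
  out
}

hca_oracle <- function(F_, p) {
  C <- dim(F_)[1]
  ex <- function(s) as.numeric(p$W2 %*% pmax(as.numeric(p$W1 %*% s + p$b1), 0) + p$b2)
  s_max <- vapply(seq_len(C), function(c) max(F_[c, , ]), 0)
  s_avg <- vapply(seq_len(C), function(c) mean(F_[c, , ]), 0)
  g <- sig_(ex(s_max) + ex(s_avg))
  out <- F_
  for (c in seq_len(C)) out[c, , ] <- g[c] * F_[c, , ]
  out
}

hsa_oracle_k1 <- function(F_, w_max, w_mean, bias) {
  d <- dim(F_)
  t1 <- apply(F_, c(2, 3), max)
  t2 <- apply(F_, c(2, 3), mean)
  t4 <- sig_(w_max * t1 + w_mean * t2 + bias)
  out <- F_
  for (c in seq_len(d[1])) out[c, , ] <- t4 * F_[c, , ]
  out
}

test_that("1D channel attention matches the hand-computed composition", {
  set.seed(1)
  F_ <- matrix(c(1, -2, 0.5, 3, -1, 2), nrow = 2)        # C=2, T=3
  p <- attention_params(2L, r = 2L, k = 1L, init = "zero")
  p$W1 <- matrix(c(0.4, -0.3), 1, 2)
  p$b1 <- 0.1
  p$W2 <- matrix(c(0.8, -0.5), 2, 1)
  p$b2 <- c(-0.2, 0.3)
  expect_equal(ca_1d(F_, p), ca_oracle(F_, p), tolerance = 1e-12)
  # random cases
  for (i in 1:5) {
    Fr <- matrix(rnorm(4 * 7), 4, 7)
    pr <- attention_params(4L, r = 2L, k = 1L)
    expect_equal(ca_1d(Fr, pr), ca_oracle(Fr, pr), tolerance = 1e-9)
    expect_true(all(abs(ca_1d(Fr, pr)) <= abs(Fr) + 1e-12))  # gate in (0,1)
  }
})

test_that("zero excitation weights give the half gate", {
  F_ <- matrix(rnorm(12), 3, 4)
  p <- attention_params(3L, init = "zero")
  expect_equal(ca_1d(F_, p), F_ / 2, tolerance = 1e-12)
  Fa <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  p2 <- attention_params(2L, k = 3L, init = "zero")
  expect_equal(hca_2d(Fa, p2), Fa / 2, tolerance = 1e-12)
  expect_equal(hsa_2d(Fa, p2), Fa / 2, tolerance = 1e-12)  # zero conv kernel
})

test_that("hybrid channel attention fuses max and average pooling branches", {
  set.seed(2)
  # constant input: both pooled vectors coincide, gate = sigmoid(2 e(c0 1))
  p <- attention_params(2L, r = 2L, k = 1L)
  Fc <- array(0.7, c(2, 3, 3))
  ex <- function(s) as.numeric(p$W2 %*% pmax(as.numeric(p$W1 %*% s + p$b1), 0) + p$b2)
  g <- sig_(2 * ex(rep(0.7, 2)))
  expect_equal(hca_2d(Fc, p), sweep(Fc, 1, g, "*"), tolerance = 1e-12)
  # toy and random cases against the brute-force oracle
  F_ <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  expect_equal(hca_2d(F_, p), hca_oracle(F_, p), tolerance = 1e-9)
  for (i in 1:4) {
    Fr <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
    pr <- attention_params(3L, r = 2L, k = 1L)
    y <- hca_2d(Fr, pr)
    expect_equal(y, hca_oracle(Fr, pr), tolerance = 1e-9)
    # channel-wise broadcast: ratio constant over spatial positions
    ratio <- y / Fr
    for (c in 1:3) expect_lt(diff(range(ratio[c, , ])), 1e-9)
  }
})

test_that("spatial attention gates every channel with one sigmoid map", {
  set.seed(3)
  F_ <- array(rnorm(1 * 3 * 3), c(1, 3, 3))
  p <- attention_params(1L, k = 1L, init = "zero")
  p$conv$W <- array(c(1, 0), c(1, 1, 2, 1))       # identity on the max map
  y <- hsa_2d(F_, p)
  expect_equal(y, hsa_oracle_k1(F_, 1, 0, 0), tolerance = 1e-12)
  # general k=1 kernels, multi-channel
  for (i in 1:4) {
    Fr <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
    pr <- attention_params(3L, k = 1L, init = "zero")
    wts <- rnorm(3)
    pr$conv$W <- array(wts[1:2], c(1, 1, 2, 1))
    pr$conv$b <- wts[3]
    y <- hsa_2d(Fr, pr)
    expect_equal(y, hsa_oracle_k1(Fr, wts[1], wts[2], wts[3]),
                 tolerance = 1e-9)
    # the gate is shared across channels
    r1 <- y[1, , ] / Fr[1, , ]
    r2 <- y[3, , ] / Fr[3, , ]
    expect_equal(r1, r2, tolerance = 1e-9)
  }
  expect_error(attention_params(3L, k = 4L), "odd")
})

test_that("serial hybrid attention is channel gate then spatial gate", {
  set.seed(4)
  F_ <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  p <- attention_params(2L, r = 2L, k = 1L)
  expect_equal(ha_2d(F_, p), hsa_2d(hca_2d(F_, p), p), tolerance = 1e-12)
  # end-to-end toy against composed brute-force oracles
  p0 <- attention_params(2L, r = 2L, k = 1L, init = "zero")
  p0$W1 <- matrix(c(0.3, 0.2), 1, 2); p0$b1 <- -0.1
  p0$W2 <- matrix(c(0.5, -0.4), 2, 1); p0$b2 <- c(0.2, 0)
  p0$conv$W <- array(c(0.7, -0.3), c(1, 1, 2, 1)); p0$conv$b <- 0.1
  mid <- hca_oracle(F_, p0)
  expect_equal(ha_2d(F_, p0), hsa_oracle_k1(mid, 0.7, -0.3, 0.1),
               tolerance = 1e-10)
})

test_that("channel permutation equivariance holds for the 1D gate", {
  set.seed(6)
  F_ <- matrix(rnorm(4 * 6), 4, 6)
  p <- attention_params(4L, r = 2L, k = 1L)
  perm <- c(3, 1, 4, 2)
  pp <- p
  pp$W1 <- p$W1[, perm]
  pp$W2 <- p$W2[perm, , drop = FALSE]
  pp$b2 <- p$b2[perm]
  expect_equal(ca_1d(F_[perm, ], pp), ca_1d(F_, p)[perm, ],
               tolerance = 1e-12)
})
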