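test_that("zero residual weights reduce a block to relu of the input", {
  # identity shortcut (same widths, stride 1), all branch weights zero:
  # H(X) = relu(0 + X)
  zero_block <- function(p) {
    for (nm in c("conv1", "conv2", "conv3")) {
      p[[nm]]$W[] <- 0; p[[nm]]$b[] <- 0
    }
    p
  }
  p1 <- zero_block(bottleneck_params_1d(8L, 2L, c_out = 8L, seed = 2))
  x1 <- matrix(rnorm(8 * 20), 8, 20)
  expect_equal(bottleneck_block_1d(x1, p1, attention_on = FALSE),
               pmax(x1, 0), tolerance = 1e-12)
  # non-negative input passes through unchanged
  xp <- abs(x1)
  expect_equal(bottleneck_block_1d(xp, p1, attention_on = FALSE), xp,
               tolerance = 1e-12)
  p2 <- zero_block(bottleneck_params_2d(4L, 2L, c_out = 4L, seed = 3))
  x2 <- array(rnorm(4 * 5 * 5), c(4, 5, 5))
  expect_equal(bottleneck_block_2d(x2, p2, attention_on = FALSE),
               pmax(x2, 0), tolerance = 1e-12)
})

test_that("a 1x1-kernel block matches hand computation", {
  # one channel, four positions, all kernels 1x1, no attention/projection:
  # the chain is scalar affine maps + batchnorm (running stats 0/1) + relu
  p <- bottleneck_params_1d(1L, 1L, c_out = 1L, kernel = 1L,
                            attention = FALSE, seed = 5)
  x <- matrix(c(0.5, -1, 2, 0.25), 1, 4)
  eps <- 1e-5
  bn <- function(v, g, b) g * (v / sqrt(1 + eps)) + b
  h <- pmax(bn(as.numeric(p$conv1$W) * x + as.numeric(p$conv1$b),
               p$bn1$gamma, p$bn1$beta), 0)
  h <- pmax(bn(as.numeric(p$conv2$W) * h + as.numeric(p$conv2$b),
               p$bn2$gamma, p$bn2$beta), 0)
  h <- bn(as.numeric(p$conv3$W) * h + as.numeric(p$conv3$b),
          p$bn3$gamma, p$bn3$beta)
  expect_equal(bottleneck_block_1d(x, p), pmax(h + x, 0), tolerance = 1e-9)
})

test_that("block output width follows expansion regardless of input width", {
  for (cin in c(3L, 8L, 12L)) {
    p <- bottleneck_params_1d(cin, 4L, seed = 1)        # c_out = 16
    y <- bottleneck_block_1d(matrix(rnorm(cin * 12), cin, 12), p)
    expect_equal(dim(y), c(16L, 12L))
    p2 <- bottleneck_params_2d(cin, 4L, seed = 1, k = 3L)
    y2 <- bottleneck_block_2d(array(rnorm(cin * 16), c(cin, 4, 4)), p2)
    expect_equal(dim(y2), c(16L, 4L, 4L))
  }
  # width mismatch without projection errors out
  p <- bottleneck_params_1d(4L, 2L, c_out = 8L, seed = 1)
  expect_error(bottleneck_block_1d(matrix(0, 3, 5), p), "channels")
})

test_that("every variant emits nine probabilities in (0,1)", {
  cfg <- micro_config()
  x1 <- array(rnorm(64 * 12 * 2), c(64, 12, 2))
  x2 <- array(runif(16 * 16 * 12 * 2), c(16, 16, 12, 2))
  for (v in c("EC-MAM", "1D-EC-SAM", "2D-EC-SAM", "EC-MMI")) {
    m <- build_model(v, cfg, seed = 4)
    p <- model_forward(m,
                       x1 = if (v != "2D-EC-SAM") x1,
                       x2 = if (v != "1D-EC-SAM") x2)
    expect_equal(dim(p), c(2L, 9L))
    expect_true(all(p > 0 & p < 1))
  }
  expect_error(build_model("EC-XXX", cfg), "unknown variant")
  expect_error(model_forward(build_model("1D-EC-SAM", cfg, 1), x1 = NULL),
               "requires")
})

test_that("attention-bypassed EC-MAM equals EC-MMI under shared weights", {
  cfg <- micro_config()
  mam <- build_model("EC-MAM", cfg, seed = 2)
  mmi <- copy_shared_weights(build_model("EC-MMI", cfg, seed = 9), mam)
  x1 <- array(rnorm(64 * 12 * 3), c(64, 12, 3))
  x2 <- array(runif(16 * 16 * 12 * 3), c(16, 16, 12, 3))
  expect_lt(max(abs(model_forward(mam, x1, x2, bypass_attention = TRUE) -
                      model_forward(mmi, x1, x2))), 1e-6)
  # the two parameter sets differ only by the attention weight names
  extra <- setdiff(names(ecmam:::flatten_params(mam$params)),
                   names(ecmam:::flatten_params(mmi$params)))
  expect_true(length(extra) > 0)
  expect_true(all(grepl("/att/", extra)))
})

test_that("inference is deterministic and reproducible from the seed", {
  cfg <- micro_config()
  m1 <- build_model("EC-MAM", cfg, seed = 11)
  m2 <- build_model("EC-MAM", cfg, seed = 11)
  set.seed(8)
  x1 <- array(rnorm(64 * 12 * 2), c(64, 12, 2))
  x2 <- array(runif(16 * 16 * 12 * 2), c(16, 16, 12, 2))
  expect_identical(model_forward(m1, x1, x2), model_forward(m2, x1, x2))
  # duplicated record in a batch gives identical rows
  pd <- model_forward(m1, x1[, , c(1, 1)], x2[, , , c(1, 1)])
  expect_identical(pd[1, ], pd[2, ])
})

test_that("parameter enumeration equals the closed-form architecture count", {
  cfg <- model_config("tiny")
  m <- build_model("EC-MAM", cfg, seed = 1)
  # independent closed-form count from the layout definition
  conv1d_n <- function(k, cin, cout) k * cin * cout + cout
  conv2d_n <- function(k, cin, cout) k * k * cin * cout + cout
  bn_n <- function(c) 2 * c
  att1d_n <- function(c, r) {
    cr <- max(1, c %/% r)
    cr * c + cr + c * cr + c
  }
  att2d_n <- function(c, r, k) att1d_n(c, r) + k * k * 2 + 1
  n <- 0
  for (two_d in c(FALSE, TRUE)) {
    cn <- if (two_d) conv2d_n else conv1d_n
    stem_k <- if (two_d) cfg$stem2d_kernel else cfg$stem1d_kernel
    n <- n + cn(stem_k, 12, cfg$widths[1]) + bn_n(cfg$widths[1])
    cin <- cfg$widths[1]
    for (s in 1:4) for (b in seq_len(cfg$stage_blocks[s])) {
      w <- cfg$widths[s]; cout <- w * cfg$expansion
      stride <- if (b == 1 && s > 1) 2 else 1
      mid_k <- if (two_d) cfg$kernel2d else cfg$kernel1d
      n <- n + cn(1, cin, w) + bn_n(w) + cn(mid_k, w, w) + bn_n(w) +
        cn(1, w, cout) + bn_n(cout)
      n <- n + if (two_d) att2d_n(cout, cfg$r, cfg$k_spatial)
               else att1d_n(cout, cfg$r)
      if (cin != cout || stride != 1) n <- n + cn(1, cin, cout) + bn_n(cout)
      cin <- cout
    }
  }
  fd <- 2 * cfg$widths[4] * cfg$expansion
  n <- n + fd * cfg$fusion_hidden + cfg$fusion_hidden +
    cfg$fusion_hidden * 9 + 9
  expect_equal(n_parameters(m), n)
})

test_that("resource accounting counts a dense layer exactly", {
  d <- ecmam:::he_dense(10L, 5L)
  expect_equal(sum(lengths(ecmam:::flatten_params(d))), 55L)
  rr <- resource_report(build_model("EC-MAM", micro_config(), seed = 1))
  expect_gt(rr$n_params, 0)
  expect_gt(rr$macs, 0)
  expect_gt(rr$storage_mb, 0)
})
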