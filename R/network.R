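#' Model configuration
#'
#' Architecture layout for the dual-channel network. The `"full"` profile is
#' the 50-layer-style bottleneck layout (stage block counts 3/4/6/3, base
#' widths 64/128/256/512, expansion 4) consuming 12 x 15000 time series and
#' 12 x 224 x 224 time-frequency stacks. The `"tiny"` profile (one block per
#' stage, widths 8/16/32/64, 12 x 1250 and 12 x 32 x 32 inputs) is small
#' enough to train on one CPU and is used throughout the test suite.
#'
#' @param profile `"full"` or `"tiny"`.
#' @param n_classes Number of output classes (default 9).
#' @param dropout Dropout rate in the fusion head (default 0.4).
#' @param r Attention reduction ratio (default 16).
#' @param k_spatial Spatial-attention kernel size (odd, default 7).
#' @param ... Named overrides for any field of the profile.
#' @return Object of class `ecmam_config`.
#' @export
model_config <- function(profile = c("tiny", "full"), n_classes = 9L,
                         dropout = 0.4, r = 16L, k_spatial = 7L, ...) {
  profile <- match.arg(profile)
  cfg <- if (profile == "full") {
    list(stage_blocks = c(3L, 4L, 6L, 3L), widths = c(64L, 128L, 256L, 512L),
         input_len = 15000L, map_size = 224L, fusion_hidden = 512L,
         fs = 500, target_s = 30, stft_window = 256L, stft_hop = 128L)
  } else {
    list(stage_blocks = c(1L, 1L, 1L, 1L), widths = c(8L, 16L, 32L, 64L),
         input_len = 1250L, map_size = 32L, fusion_hidden = 64L,
         fs = 125, target_s = 10, stft_window = 64L, stft_hop = 32L)
  }
  cfg <- utils::modifyList(cfg, list(
    profile = profile, n_classes = as.integer(n_classes), in_leads = 12L,
    expansion = 4L, kernel1d = 7L, stem1d_kernel = 15L,
    kernel2d = 3L, stem2d_kernel = 7L,
    r = as.integer(r), k_spatial = as.integer(k_spatial),
    dropout = dropout))
  dots <- list(...)
  if (length(dots)) cfg <- utils::modifyList(cfg, dots)
  if (cfg$dropout < 0 || cfg$dropout >= 1) stopf("dropout must be in [0,1)")
  if (any(cfg$widths < 1L)) stopf("widths must be >= 1")
  structure(cfg, class = "ecmam_config")
}

att1d_init <- function(C, r) {
  cr <- max(1L, C %/% r)
  list(W1 = he_dense(C, cr)$W, b1 = numeric(cr),
       W2 = he_dense(cr, C)$W, b2 = numeric(C))
}

att2d_init <- function(C, r, k) {
  c(att1d_init(C, r), list(conv = he_conv2d(k, k, 2L, 1L), k = k))
}

block1d_init <- function(Cin, w, Cout, kmid, stride, attention, r) {
  p <- list(conv1 = he_conv1d(1L, Cin, w), bn1 = bn_init(w),
            conv2 = he_conv1d(kmid, w, w), bn2 = bn_init(w),
            conv3 = he_conv1d(1L, w, Cout), bn3 = bn_init(Cout),
            stride = stride, kmid = kmid)
  if (attention) p$att <- att1d_init(Cout, r)
  if (Cin != Cout || stride != 1L)
    p$proj <- list(conv = he_conv1d(1L, Cin, Cout), bn = bn_init(Cout))
  p
}

block2d_init <- function(Cin, w, Cout, kmid, stride, attention, r, k) {
  p <- list(conv1 = he_conv2d(1L, 1L, Cin, w), bn1 = bn_init(w),
            conv2 = he_conv2d(kmid, kmid, w, w), bn2 = bn_init(w),
            conv3 = he_conv2d(1L, 1L, w, Cout), bn3 = bn_init(Cout),
            stride = stride, kmid = kmid)
  if (attention) p$att <- att2d_init(Cout, r, k)
  if (Cin != Cout || stride != 1L)
    p$proj <- list(conv = he_conv2d(1L, 1L, Cin, Cout), bn = bn_init(Cout))
  p
}

block1d_run <- function(x, p, training = FALSE, bypass = FALSE) {
  c1 <- conv1d_fw(x, p$conv1$W, p$conv1$b)
  b1 <- bn_fw(c1$y, p$bn1, training); r1 <- relu_fw(b1$y)
  c2 <- conv1d_fw(r1$y, p$conv2$W, p$conv2$b, stride = p$stride,
                  pad = (p$kmid - 1L) %/% 2L)
  b2 <- bn_fw(c2$y, p$bn2, training); r2 <- relu_fw(b2$y)
  c3 <- conv1d_fw(r2$y, p$conv3$W, p$conv3$b)
  b3 <- bn_fw(c3$y, p$bn3, training)
  at <- if (!is.null(p$att) && !bypass) ca1d_fw(b3$y, p$att)
        else list(y = b3$y, cache = NULL)
  if (!is.null(p$proj)) {
    pc <- conv1d_fw(x, p$proj$conv$W, p$proj$conv$b, stride = p$stride)
    pb <- bn_fw(pc$y, p$proj$bn, training)
    sc <- pb$y
  } else { pc <- pb <- NULL; sc <- x }
  out <- relu_fw(at$y + sc)
  list(y = out$y,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    c3 = c3$cache, b3 = b3$cache, at = at$cache,
                    pc = if (!is.null(pc)) pc$cache,
                    pb = if (!is.null(pb)) pb$cache,
                    out = out$cache, bypass = bypass))
}

block1d_grad <- function(dy, cache, p) {
  ds <- relu_bw(dy, cache$out)
  g <- list()
  if (!is.null(p$proj)) {
    pbb <- bn_bw(ds, cache$pb)
    pcb <- conv1d_bw(pbb$dx, cache$pc)
    g$proj <- list(conv = list(W = pcb$dW, b = pcb$db),
                   bn = list(gamma = pbb$dgamma, beta = pbb$dbeta))
    dx_sc <- pcb$dx
  } else dx_sc <- ds
  if (!is.null(p$att) && !cache$bypass) {
    ab <- ca1d_bw(ds, cache$at, p$att)
    g$att <- list(W1 = ab$dW1, b1 = ab$db1, W2 = ab$dW2, b2 = ab$db2)
    d3 <- ab$dx
  } else d3 <- ds
  b3b <- bn_bw(d3, cache$b3)
  g$bn3 <- list(gamma = b3b$dgamma, beta = b3b$dbeta)
  c3b <- conv1d_bw(b3b$dx, cache$c3)
  g$conv3 <- list(W = c3b$dW, b = c3b$db)
  d2 <- relu_bw(c3b$dx, cache$r2)
  b2b <- bn_bw(d2, cache$b2)
  g$bn2 <- list(gamma = b2b$dgamma, beta = b2b$dbeta)
  c2b <- conv1d_bw(b2b$dx, cache$c2)
  g$conv2 <- list(W = c2b$dW, b = c2b$db)
  d1 <- relu_bw(c2b$dx, cache$r1)
  b1b <- bn_bw(d1, cache$b1)
  g$bn1 <- list(gamma = b1b$dgamma, beta = b1b$dbeta)
  c1b <- conv1d_bw(b1b$dx, cache$c1)
  g$conv1 <- list(W = c1b$dW, b = c1b$db)
  list(dx = c1b$dx + dx_sc, grads = g)
}

block2d_run <- function(x, p, training = FALSE, bypass = FALSE) {
  c1 <- conv2d_fw(x, p$conv1$W, p$conv1$b)
  b1 <- bn_fw(c1$y, p$bn1, training); r1 <- relu_fw(b1$y)
  c2 <- conv2d_fw(r1$y, p$conv2$W, p$conv2$b, stride = p$stride,
                  pad = (p$kmid - 1L) %/% 2L)
  b2 <- bn_fw(c2$y, p$bn2, training); r2 <- relu_fw(b2$y)
  c3 <- conv2d_fw(r2$y, p$conv3$W, p$conv3$b)
  b3 <- bn_fw(c3$y, p$bn3, training)
  if (!is.null(p$att) && !bypass) {
    ca <- hca2d_fw(b3$y, p$att)
    sa <- hsa2d_fw(ca$y, p$att)
    at_y <- sa$y
    at_cache <- list(ca = ca$cache, sa = sa$cache)
  } else { at_y <- b3$y; at_cache <- NULL }
  if (!is.null(p$proj)) {
    pc <- conv2d_fw(x, p$proj$conv$W, p$proj$conv$b, stride = p$stride)
    pb <- bn_fw(pc$y, p$proj$bn, training)
    sc <- pb$y
  } else { pc <- pb <- NULL; sc <- x }
  out <- relu_fw(at_y + sc)
  list(y = out$y,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, r2 = r2$cache,
                    c3 = c3$cache, b3 = b3$cache, at = at_cache,
                    pc = if (!is.null(pc)) pc$cache,
                    pb = if (!is.null(pb)) pb$cache,
                    out = out$cache, bypass = bypass))
}

block2d_grad <- function(dy, cache, p) {
  ds <- relu_bw(dy, cache$out)
  g <- list()
  if (!is.null(p$proj)) {
    pbb <- bn_bw(ds, cache$pb)
    pcb <- conv2d_bw(pbb$dx, cache$pc)
    g$proj <- list(conv = list(W = pcb$dW, b = pcb$db),
                   bn = list(gamma = pbb$dgamma, beta = pbb$dbeta))
    dx_sc <- pcb$dx
  } else dx_sc <- ds
  if (!is.null(p$att) && !cache$bypass) {
    sb <- hsa2d_bw(ds, cache$at$sa, p$att)
    cb <- hca2d_bw(sb$dx, cache$at$ca, p$att)
    g$att <- list(W1 = cb$dW1, b1 = cb$db1, W2 = cb$dW2, b2 = cb$db2,
                  conv = list(W = sb$dconv_W, b = sb$dconv_b))
    d3 <- cb$dx
  } else d3 <- ds
  b3b <- bn_bw(d3, cache$b3)
  g$bn3 <- list(gamma = b3b$dgamma, beta = b3b$dbeta)
  c3b <- conv2d_bw(b3b$dx, cache$c3)
  g$conv3 <- list(W = c3b$dW, b = c3b$db)
  d2 <- relu_bw(c3b$dx, cache$r2)
  b2b <- bn_bw(d2, cache$b2)
  g$bn2 <- list(gamma = b2b$dgamma, beta = b2b$dbeta)
  c2b <- conv2d_bw(b2b$dx, cache$c2)
  g$conv2 <- list(W = c2b$dW, b = c2b$db)
  d1 <- relu_bw(c2b$dx, cache$r1)
  b1b <- bn_bw(d1, cache$b1)
  g$bn1 <- list(gamma = b1b$dgamma, beta = b1b$dbeta)
  c1b <- conv2d_bw(b1b$dx, cache$c1)
  g$conv1 <- list(W = c1b$dW, b = c1b$db)
  list(dx = c1b$dx + dx_sc, grads = g)
}

branch1d_init <- function(cfg, attention = TRUE) {
  w <- cfg$widths; e <- cfg$expansion
  P <- list(stem = list(conv = he_conv1d(cfg$stem1d_kernel, cfg$in_leads,
                                         w[1]),
                        bn = bn_init(w[1])))
  cin <- w[1]
  for (s in 1:4) {
    stage <- list()
    for (b in seq_len(cfg$stage_blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      stage[[paste0("block", b)]] <-
        block1d_init(cin, w[s], w[s] * e, cfg$kernel1d, stride,
                     attention, cfg$r)
      cin <- w[s] * e
    }
    P[[paste0("stage", s)]] <- stage
  }
  P
}

branch2d_init <- function(cfg, attention = TRUE) {
  w <- cfg$widths; e <- cfg$expansion
  P <- list(stem = list(conv = he_conv2d(cfg$stem2d_kernel, cfg$stem2d_kernel,
                                         cfg$in_leads, w[1]),
                        bn = bn_init(w[1])))
  cin <- w[1]
  for (s in 1:4) {
    stage <- list()
    for (b in seq_len(cfg$stage_blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      stage[[paste0("block", b)]] <-
        block2d_init(cin, w[s], w[s] * e, cfg$kernel2d, stride,
                     attention, cfg$r, cfg$k_spatial)
      cin <- w[s] * e
    }
    P[[paste0("stage", s)]] <- stage
  }
  P
}

branch1d_run <- function(x, P, cfg, training = FALSE, bypass = FALSE) {
  st <- conv1d_fw(x, P$stem$conv$W, P$stem$conv$b, stride = 2L,
                  pad = (cfg$stem1d_kernel - 1L) %/% 2L)
  sb <- bn_fw(st$y, P$stem$bn, training)
  sr <- relu_fw(sb$y)
  sp <- maxpool1d_fw(sr$y)
  caches <- list(stem = list(conv = st$cache, bn = sb$cache, relu = sr$cache,
                             pool = sp$cache))
  h <- sp$y
  for (s in 1:4) for (b in seq_len(cfg$stage_blocks[s])) {
    nm <- paste0("stage", s, "/block", b)
    blk <- block1d_run(h, P[[paste0("stage", s)]][[paste0("block", b)]],
                       training, bypass)
    caches[[nm]] <- blk$cache
    h <- blk$y
  }
  gp <- gap_fw(h)
  caches$gap <- gp$cache
  list(feat = gp$y, caches = caches)
}

branch1d_grad <- function(dfeat, caches, P, cfg) {
  dh <- gap_bw(dfeat, caches$gap)
  G <- list()
  for (s in 4:1) for (b in rev(seq_len(cfg$stage_blocks[s]))) {
    nm <- paste0("stage", s, "/block", b)
    bg <- block1d_grad(dh, caches[[nm]],
                       P[[paste0("stage", s)]][[paste0("block", b)]])
    if (is.null(G[[paste0("stage", s)]])) G[[paste0("stage", s)]] <- list()
    G[[paste0("stage", s)]][[paste0("block", b)]] <- bg$grads
    dh <- bg$dx
  }
  dp <- maxpool1d_bw(dh, caches$stem$pool)
  dr <- relu_bw(dp, caches$stem$relu)
  bb <- bn_bw(dr, caches$stem$bn)
  cb <- conv1d_bw(bb$dx, caches$stem$conv)
  G$stem <- list(conv = list(W = cb$dW, b = cb$db),
                 bn = list(gamma = bb$dgamma, beta = bb$dbeta))
  G
}

branch2d_run <- function(x, P, cfg, training = FALSE, bypass = FALSE) {
  st <- conv2d_fw(x, P$stem$conv$W, P$stem$conv$b, stride = 2L,
                  pad = (cfg$stem2d_kernel - 1L) %/% 2L)
  sb <- bn_fw(st$y, P$stem$bn, training)
  sr <- relu_fw(sb$y)
  sp <- maxpool2d_fw(sr$y)
  caches <- list(stem = list(conv = st$cache, bn = sb$cache, relu = sr$cache,
                             pool = sp$cache))
  h <- sp$y
  for (s in 1:4) for (b in seq_len(cfg$stage_blocks[s])) {
    nm <- paste0("stage", s, "/block", b)
    blk <- block2d_run(h, P[[paste0("stage", s)]][[paste0("block", b)]],
                       training, bypass)
    caches[[nm]] <- blk$cache
    h <- blk$y
  }
  gp <- gap_fw(h)
  caches$gap <- gp$cache
  list(feat = gp$y, caches = caches)
}

branch2d_grad <- function(dfeat, caches, P, cfg) {
  dh <- gap_bw(dfeat, caches$gap)
  G <- list()
  for (s in 4:1) for (b in rev(seq_len(cfg$stage_blocks[s]))) {
    nm <- paste0("stage", s, "/block", b)
    bg <- block2d_grad(dh, caches[[nm]],
                       P[[paste0("stage", s)]][[paste0("block", b)]])
    if (is.null(G[[paste0("stage", s)]])) G[[paste0("stage", s)]] <- list()
    G[[paste0("stage", s)]][[paste0("block", b)]] <- bg$grads
    dh <- bg$dx
  }
  dp <- maxpool2d_bw(dh, caches$stem$pool)
  dr <- relu_bw(dp, caches$stem$relu)
  bb <- bn_bw(dr, caches$stem$bn)
  cb <- conv2d_bw(bb$dx, caches$stem$conv)
  G$stem <- list(conv = list(W = cb$dW, b = cb$db),
                 bn = list(gamma = bb$dgamma, beta = bb$dbeta))
  G
}

model_variants <- function() c("EC-MAM", "1D-EC-SAM", "2D-EC-SAM", "EC-MMI")

#' Build a classification network
#'
#' Assembles one of the four model variants: `"EC-MAM"` (both branches with
#' attention, fused), `"1D-EC-SAM"` / `"2D-EC-SAM"` (single branch with
#' attention) and `"EC-MMI"` (both branches, no attention parameters —
#' equivalent to EC-MAM with every gate forced open).
#'
#' @param variant One of `model_variants()`.
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `ecmam_model`.
#' @export
build_model <- function(variant = "EC-MAM", cfg = model_config("tiny"),
                        seed = 1L) {
  if (!variant %in% model_variants())
    stopf("unknown variant '%s' (expected one of %s)", variant,
          paste(model_variants(), collapse = ", "))
  stopifnot(inherits(cfg, "ecmam_config"))
  attention <- variant != "EC-MMI"
  use_1d <- variant %in% c("EC-MAM", "1D-EC-SAM", "EC-MMI")
  use_2d <- variant %in% c("EC-MAM", "2D-EC-SAM", "EC-MMI")
  feat_dim <- cfg$widths[4] * cfg$expansion
  with_seed(seed, {
    params <- list()
    if (use_1d) params$b1d <- branch1d_init(cfg, attention)
    if (use_2d) params$b2d <- branch2d_init(cfg, attention)
    in_dim <- feat_dim * (use_1d + use_2d)
    params$head <- list(fc1 = he_dense(in_dim, cfg$fusion_hidden),
                        fc2 = he_dense(cfg$fusion_hidden, cfg$n_classes))
    structure(list(variant = variant, cfg = cfg, params = params,
                   seed = seed),
              class = "ecmam_model")
  })
}

#' @export
print.ecmam_model <- function(x, ...) {
  cat(sprintf("<ecmam_model %s, %s profile> %s parameters\n", x$variant,
              x$cfg$profile,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Forward pass
#'
#' Runs the network on a batch and returns per-class probabilities
#' (elementwise sigmoid over the 9 logits). Inference mode (`training =
#' FALSE`) disables dropout and uses running batch-norm statistics, so the
#' output is deterministic given weights and inputs.
#'
#' @param model An `ecmam_model` from [build_model()].
#' @param x1 1D inputs: `T x 12 x N` array (or `12 x T` matrix for a single
#'   record), required unless the variant is 2D-only.
#' @param x2 2D inputs: `S x S x 12 x N` array (or a single `12 x S x S`
#'   `ecg_tfmap`), required unless the variant is 1D-only.
#' @param training Enable dropout and batch-statistics mode.
#' @param bypass_attention Force every attention gate to 1 (identity);
#'   mechanism behind the attention ablation.
#' @param keep_caches Keep layer caches for backpropagation (internal).
#' @return `N x n_classes` matrix of probabilities in (0,1), or a list with
#'   caches when `keep_caches = TRUE`.
#' @export
model_forward <- function(model, x1 = NULL, x2 = NULL, training = FALSE,
                          bypass_attention = FALSE, keep_caches = FALSE) {
  stopifnot(inherits(model, "ecmam_model"))
  cfg <- model$cfg
  use_1d <- !is.null(model$params$b1d)
  use_2d <- !is.null(model$params$b2d)
  if (use_1d) {
    x1 <- coerce_x1(x1, cfg)
    n <- dim(x1)[3]
  }
  if (use_2d) {
    x2 <- coerce_x2(x2, cfg)
    n2 <- dim(x2)[4]
    if (use_1d && n2 != n) stopf("x1 and x2 batch sizes differ (%d vs %d)",
                                 n, n2)
    n <- n2
  }
  feats <- list(); caches <- list()
  if (use_1d) {
    r1 <- branch1d_run(x1, model$params$b1d, cfg, training, bypass_attention)
    feats$b1d <- r1$feat; caches$b1d <- r1$caches
  }
  if (use_2d) {
    r2 <- branch2d_run(x2, model$params$b2d, cfg, training, bypass_attention)
    feats$b2d <- r2$feat; caches$b2d <- r2$caches
  }
  feat <- do.call(rbind, unname(feats))
  f1 <- dense_fw(feat, model$params$head$fc1$W, model$params$head$fc1$b)
  fr <- relu_fw(f1$y)
  dr <- dropout_fw(fr$y, cfg$dropout, training)
  f2 <- dense_fw(dr$y, model$params$head$fc2$W, model$params$head$fc2$b)
  probs <- t(sigmoid(f2$y))
  colnames(probs) <- class_vocabulary()[seq_len(cfg$n_classes)]
  if (!keep_caches) return(probs)
  list(probs = probs, logits = f2$y,
       caches = list(branches = caches, feat_dims = vapply(feats, nrow, 0L),
                     f1 = f1$cache, fr = fr$cache, dr = dr$cache,
                     f2 = f2$cache))
}

# Gradient of the whole model given dL/dlogits (n_classes x N).
model_backward <- function(model, fwd, dlogits) {
  cfg <- model$cfg
  G <- list()
  f2b <- dense_bw(dlogits, fwd$caches$f2)
  drb <- dropout_bw(f2b$dx, fwd$caches$dr)
  frb <- relu_bw(drb, fwd$caches$fr)
  f1b <- dense_bw(frb, fwd$caches$f1)
  G$head <- list(fc1 = list(W = f1b$dW, b = f1b$db),
                 fc2 = list(W = f2b$dW, b = f2b$db))
  dfeat <- f1b$dx
  fd <- fwd$caches$feat_dims
  offset <- 0L
  if (!is.null(model$params$b1d)) {
    d1 <- dfeat[offset + seq_len(fd[["b1d"]]), , drop = FALSE]
    offset <- offset + fd[["b1d"]]
    G$b1d <- branch1d_grad(d1, fwd$caches$branches$b1d, model$params$b1d, cfg)
  }
  if (!is.null(model$params$b2d)) {
    d2 <- dfeat[offset + seq_len(fd[["b2d"]]), , drop = FALSE]
    G$b2d <- branch2d_grad(d2, fwd$caches$branches$b2d, model$params$b2d, cfg)
  }
  G
}

coerce_x1 <- function(x1, cfg) {
  if (is.null(x1)) stopf("this variant requires the 1D input x1")
  if (is.matrix(x1) || inherits(x1, "ecg_input1d")) {
    xm <- unclass(x1)
    x1 <- array(t(xm), c(ncol(xm), nrow(xm), 1L))
  }
  d <- dim(x1)
  if (length(d) != 3L || d[1] != cfg$input_len || d[2] != cfg$in_leads)
    stopf("x1 must be %d x %d x N, got %s", cfg$input_len, cfg$in_leads,
          paste(d, collapse = " x "))
  x1
}

coerce_x2 <- function(x2, cfg) {
  if (is.null(x2)) stopf("this variant requires the 2D input x2")
  if (inherits(x2, "ecg_tfmap") ||
      (is.array(x2) && length(dim(x2)) == 3L)) {
    x2 <- array(aperm(unclass(x2), c(2L, 3L, 1L)),
                c(dim(x2)[2], dim(x2)[3], dim(x2)[1], 1L))
  }
  d <- dim(x2)
  if (length(d) != 4L || d[1] != cfg$map_size || d[2] != cfg$map_size ||
      d[3] != cfg$in_leads)
    stopf("x2 must be %d x %d x %d x N, got %s", cfg$map_size, cfg$map_size,
          cfg$in_leads, paste(d, collapse = " x "))
  x2
}

# ---- exported single-sample block operations -------------------------------

#' Bottleneck residual block parameters
#'
#' Random (He-initialised) weights for one bottleneck residual block:
#' 1x1 reduce, middle convolution, 1x1 expand, each followed by batch
#' normalisation, an optional channel-attention (1D) or hybrid-attention
#' (2D) gate on the residual branch, and a projection shortcut when the
#' input/output widths or strides differ.
#'
#' @param c_in Input channels.
#' @param width Bottleneck width (channels of the middle convolution).
#' @param c_out Output channels (default `4 * width`).
#' @param kernel Middle convolution kernel size.
#' @param stride Stride of the middle convolution (and the shortcut).
#' @param attention Include the attention gate.
#' @param r Attention reduction ratio.
#' @param k Spatial-attention kernel (2D only).
#' @param seed RNG seed for the weights.
#' @return Parameter list consumed by [bottleneck_block_1d()] /
#'   [bottleneck_block_2d()].
#' @export
bottleneck_params_1d <- function(c_in, width, c_out = 4L * width,
                                 kernel = 7L, stride = 1L, attention = TRUE,
                                 r = 16L, seed = 1L) {
  with_seed(seed, block1d_init(c_in, width, c_out, kernel, stride,
                               attention, r))
}

#' @rdname bottleneck_params_1d
#' @export
bottleneck_params_2d <- function(c_in, width, c_out = 4L * width,
                                 kernel = 3L, stride = 1L, attention = TRUE,
                                 r = 16L, k = 7L, seed = 1L) {
  with_seed(seed, block2d_init(c_in, width, c_out, kernel, stride,
                               attention, r, k))
}

#' Apply a bottleneck residual block (inference mode)
#'
#' `y = relu(attention(F(x)) + shortcut(x))` where `F` is the
#' reduce/convolve/expand residual branch. Batch normalisation runs with its
#' stored running statistics (fresh parameters give mean 0, variance 1).
#'
#' @param x `C x T` matrix (1D) or `C x H x W` array (2D).
#' @param params From [bottleneck_params_1d()] / [bottleneck_params_2d()].
#' @param attention_on Apply the attention gate (if the block has one);
#'   `FALSE` bypasses it (identity gate).
#' @return Output feature map, channels first.
#' @export
bottleneck_block_1d <- function(x, params, attention_on = TRUE) {
  assert_finite_matrix(x, "x")
  if (dim(params$conv1$W)[2] != nrow(x))
    stopf("block expects %d input channels, got %d (supply a projection)",
          dim(params$conv1$W)[2], nrow(x))
  xa <- array(t(x), c(ncol(x), nrow(x), 1L))
  y <- block1d_run(xa, params, training = FALSE,
                   bypass = !attention_on)$y
  t(y[, , 1L])
}

#' @rdname bottleneck_block_1d
#' @export
bottleneck_block_2d <- function(x, params, attention_on = TRUE) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  if (dim(params$conv1$W)[3] != dim(x)[1])
    stopf("block expects %d input channels, got %d (supply a projection)",
          dim(params$conv1$W)[3], dim(x)[1])
  xa <- aperm(x, c(2L, 3L, 1L))
  dim(xa) <- c(dim(xa), 1L)
  y <- block2d_run(xa, params, training = FALSE,
                   bypass = !attention_on)$y
  dim(y) <- dim(y)[1:3]
  aperm(y, c(3L, 1L, 2L))
}

# ---- parameter traversal ---------------------------------------------------

.flatten_skip <- c("stats", "stride", "kmid", "k", "channels", "r")

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    if (nm %in% .flatten_skip) next
    v <- p[[nm]]
    key <- if (prefix == "") nm else paste(prefix, nm, sep = "/")
    if (is.list(v)) out <- c(out, flatten_params(v, key))
    else if (is.numeric(v)) out[[key]] <- v
  }
  out
}

param_path <- function(name) strsplit(name, "/", fixed = TRUE)[[1L]]

#' Number of trainable parameters
#'
#' @param model An `ecmam_model`.
#' @return Integer count of trainable weight elements (batch-norm running
#'   statistics excluded).
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_params(model$params), length, 0L))
}

# Deep copy including batch-norm running-statistic environments.
clone_model <- function(model) {
  cl <- function(x) {
    if (is.environment(x)) {
      e <- new.env(parent = emptyenv())
      for (nm in ls(x)) assign(nm, get(nm, envir = x), envir = e)
      e
    } else if (is.list(x)) {
      structure(lapply(x, cl), class = class(x), names = names(x))
    } else x
  }
  out <- model
  out$params <- cl(model$params)
  out
}
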