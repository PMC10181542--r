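# Neural-network primitives with explicit forward/backward passes.
# Layouts: 1D feature maps are (T, C, N) arrays (time, channel, batch);
# 2D maps are (H, W, C, N). Convolutions run as im2col gathers followed by
# one BLAS GEMM; backward scatters with rowsum(). Index maps are cached per
# shape. Correctness is pinned by finite-difference tests.

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .idx_cache)
  }
  v
}

conv1d_idx <- function(Tin, C, k, stride, pad) {
  key <- paste("c1", Tin, C, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Tp <- Tin + 2L * pad
    L <- (Tp - k) %/% stride + 1L
    offs <- as.vector(outer(seq_len(k), (seq_len(C) - 1L) * Tp, "+"))  # K
    idx <- outer(offs, (seq_len(L) - 1L) * stride, "+")                # K x L
    list(idxv = as.vector(idx), K = k * C, L = L, Tp = Tp)
  })
}

conv2d_idx <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste("c2", H, W, C, kh, kw, stride, pad, sep = "_")
  cache_get(key, function() {
    Hp <- H + 2L * pad; Wp <- W + 2L * pad
    Ho <- (Hp - kh) %/% stride + 1L
    Wo <- (Wp - kw) %/% stride + 1L
    offs <- as.vector(outer(
      as.vector(outer(seq_len(kh), (seq_len(kw) - 1L) * Hp, "+")),
      (seq_len(C) - 1L) * Hp * Wp, "+"))                       # K = kh*kw*C
    starts <- as.vector(outer((seq_len(Ho) - 1L) * stride,
                              (seq_len(Wo) - 1L) * stride * Hp, "+"))  # L
    idx <- outer(offs, starts, "+")
    list(idxv = as.vector(idx), K = kh * kw * C, L = Ho * Wo,
         Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  })
}

pad_1d <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1] + 2L * pad, d[2], d[3]))
  xp[pad + seq_len(d[1]), , ] <- x
  xp
}

pad_2d <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

# ---- conv1d ----------------------------------------------------------------

conv1d_fw <- function(x, W, b, stride = 1L, pad = 0L) {
  d <- dim(x)
  k <- dim(W)[1]; Fo <- dim(W)[3]
  stopifnot(dim(W)[2] == d[2])
  ii <- conv1d_idx(d[1], d[2], k, as.integer(stride), as.integer(pad))
  xp <- pad_1d(x, pad)
  dim(xp) <- c(ii$Tp * d[2], d[3])
  colm <- xp[ii$idxv, , drop = FALSE]
  dim(colm) <- c(ii$K, ii$L * d[3])
  out <- crossprod(matrix(W, ii$K, Fo), colm) + b
  dim(out) <- c(Fo, ii$L, d[3])
  list(y = aperm(out, c(2L, 1L, 3L)),
       cache = list(colm = colm, dims = d, ii = ii, W = W,
                    stride = stride, pad = pad))
}

conv1d_bw <- function(dy, cache) {
  ii <- cache$ii; d <- cache$dims
  Fo <- dim(cache$W)[3]
  dym <- aperm(dy, c(2L, 1L, 3L))
  dim(dym) <- c(Fo, ii$L * d[3])
  dW <- array(t(tcrossprod(dym, cache$colm)), dim(cache$W))
  db <- rowSums(dym)
  dcol <- matrix(cache$W, ii$K, Fo) %*% dym
  dim(dcol) <- c(ii$K * ii$L, d[3])
  agg <- rowsum(dcol, ii$idxv)
  dxp <- matrix(0, ii$Tp * d[2], d[3])
  dxp[as.integer(rownames(agg)), ] <- agg
  dim(dxp) <- c(ii$Tp, d[2], d[3])
  dx <- if (cache$pad > 0L)
    dxp[cache$pad + seq_len(d[1]), , , drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- conv2d ----------------------------------------------------------------

conv2d_fw <- function(x, W, b, stride = 1L, pad = 0L) {
  d <- dim(x)
  kh <- dim(W)[1]; kw <- dim(W)[2]; Fo <- dim(W)[4]
  stopifnot(dim(W)[3] == d[3])
  ii <- conv2d_idx(d[1], d[2], d[3], kh, kw, as.integer(stride),
                   as.integer(pad))
  xp <- pad_2d(x, pad)
  dim(xp) <- c(ii$Hp * ii$Wp * d[3], d[4])
  colm <- xp[ii$idxv, , drop = FALSE]
  dim(colm) <- c(ii$K, ii$L * d[4])
  out <- crossprod(matrix(W, ii$K, Fo), colm) + b
  dim(out) <- c(Fo, ii$Ho, ii$Wo, d[4])
  list(y = aperm(out, c(2L, 3L, 1L, 4L)),
       cache = list(colm = colm, dims = d, ii = ii, W = W,
                    stride = stride, pad = pad))
}

conv2d_bw <- function(dy, cache) {
  ii <- cache$ii; d <- cache$dims
  Fo <- dim(cache$W)[4]
  dym <- aperm(dy, c(3L, 1L, 2L, 4L))
  dim(dym) <- c(Fo, ii$L * d[4])
  dW <- array(t(tcrossprod(dym, cache$colm)), dim(cache$W))
  db <- rowSums(dym)
  dcol <- matrix(cache$W, ii$K, Fo) %*% dym
  dim(dcol) <- c(ii$K * ii$L, d[4])
  agg <- rowsum(dcol, ii$idxv)
  dxp <- matrix(0, ii$Hp * ii$Wp * d[3], d[4])
  dxp[as.integer(rownames(agg)), ] <- agg
  dim(dxp) <- c(ii$Hp, ii$Wp, d[3], d[4])
  dx <- if (cache$pad > 0L)
    dxp[cache$pad + seq_len(d[1]), cache$pad + seq_len(d[2]), , ,
        drop = FALSE] else dxp
  list(dx = dx, dW = dW, db = db)
}

# ---- max pooling (overlap-safe backward) -----------------------------------

pool1d_idx <- function(Tin, k, stride, pad) {
  key <- paste("p1", Tin, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Tp <- Tin + 2L * pad
    L <- (Tp - k) %/% stride + 1L
    idx <- outer(seq_len(k), (seq_len(L) - 1L) * stride, "+")  # k x L
    list(idxm = idx, L = L, Tp = Tp)
  })
}

maxpool1d_fw <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  ii <- pool1d_idx(d[1], k, stride, pad)
  xp <- pad_1d(x, pad, value = -Inf)
  dim(xp) <- c(ii$Tp, d[2] * d[3])
  col <- xp[as.vector(ii$idxm), , drop = FALSE]
  dim(col) <- c(k, ii$L * d[2] * d[3])
  m <- col[1L, ]; am <- rep(1L, length(m))
  if (k > 1L) for (j in 2:k) {
    upd <- col[j, ] > m
    m[upd] <- col[j, upd]; am[upd] <- j
  }
  y <- m; dim(y) <- c(ii$L, d[2], d[3])
  list(y = y, cache = list(am = am, ii = ii, dims = d, k = k, pad = pad))
}

maxpool1d_bw <- function(dy, cache) {
  d <- cache$dims; ii <- cache$ii
  ncols <- d[2] * d[3]
  l <- rep(seq_len(ii$L), times = ncols)
  cn <- rep(seq_len(ncols), each = ii$L)
  sp <- cache$ii$idxm[cache$am + (l - 1L) * cache$k]
  lin <- sp + (cn - 1L) * ii$Tp
  agg <- rowsum(as.numeric(dy), lin)
  dxp <- numeric(ii$Tp * ncols)
  dxp[as.integer(rownames(agg))] <- agg
  dim(dxp) <- c(ii$Tp, d[2], d[3])
  if (cache$pad > 0L) dxp[cache$pad + seq_len(d[1]), , , drop = FALSE]
  else dxp
}

pool2d_idx <- function(H, W, k, stride, pad) {
  key <- paste("p2", H, W, k, stride, pad, sep = "_")
  cache_get(key, function() {
    Hp <- H + 2L * pad; Wp <- W + 2L * pad
    Ho <- (Hp - k) %/% stride + 1L
    Wo <- (Wp - k) %/% stride + 1L
    offs <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * Hp, "+"))
    starts <- as.vector(outer((seq_len(Ho) - 1L) * stride,
                              (seq_len(Wo) - 1L) * stride * Hp, "+"))
    idx <- outer(offs, starts, "+")                  # k^2 x L
    list(idxm = idx, K = k * k, L = Ho * Wo, Ho = Ho, Wo = Wo,
         Hp = Hp, Wp = Wp)
  })
}

maxpool2d_fw <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  ii <- pool2d_idx(d[1], d[2], k, stride, pad)
  xp <- pad_2d(x, pad, value = -Inf)
  dim(xp) <- c(ii$Hp * ii$Wp, d[3] * d[4])
  col <- xp[as.vector(ii$idxm), , drop = FALSE]
  dim(col) <- c(ii$K, ii$L * d[3] * d[4])
  m <- col[1L, ]; am <- rep(1L, length(m))
  for (j in 2:ii$K) {
    upd <- col[j, ] > m
    m[upd] <- col[j, upd]; am[upd] <- j
  }
  y <- m; dim(y) <- c(ii$Ho, ii$Wo, d[3], d[4])
  list(y = y, cache = list(am = am, ii = ii, dims = d, pad = pad))
}

maxpool2d_bw <- function(dy, cache) {
  d <- cache$dims; ii <- cache$ii
  ncols <- d[3] * d[4]
  l <- rep(seq_len(ii$L), times = ncols)
  cn <- rep(seq_len(ncols), each = ii$L)
  sp <- ii$idxm[cache$am + (l - 1L) * ii$K]
  lin <- sp + (cn - 1L) * ii$Hp * ii$Wp
  agg <- rowsum(as.numeric(dy), lin)
  dxp <- numeric(ii$Hp * ii$Wp * ncols)
  dxp[as.integer(rownames(agg))] <- agg
  dim(dxp) <- c(ii$Hp, ii$Wp, d[3], d[4])
  if (cache$pad > 0L)
    dxp[cache$pad + seq_len(d[1]), cache$pad + seq_len(d[2]), , ,
        drop = FALSE]
  else dxp
}

# ---- batch normalization ---------------------------------------------------
# Channel axis is the second-to-last dimension. Running statistics live in an
# environment on the parameter set so training updates them in place.

bn_init <- function(C) {
  st <- new.env(parent = emptyenv())
  st$rm <- numeric(C)
  st$rv <- rep(1, C)
  list(gamma = rep(1, C), beta = numeric(C), stats = st)
}

bn_fw <- function(x, p, training = FALSE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  nd <- length(d)
  C <- d[nd - 1L]; N <- d[nd]
  S <- prod(d[-c(nd - 1L, nd)])
  xr <- x; dim(xr) <- c(S, C, N)
  xm <- aperm(xr, c(1L, 3L, 2L)); dim(xm) <- c(S * N, C)
  m <- S * N
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    va[va < 0] <- 0
    p$stats$rm <- (1 - momentum) * p$stats$rm + momentum * mu
    p$stats$rv <- (1 - momentum) * p$stats$rv +
      momentum * va * m / max(m - 1, 1)
  } else {
    mu <- p$stats$rm
    va <- p$stats$rv
  }
  inv <- 1 / sqrt(va + eps)
  xh <- (xm - rep(mu, each = m)) * rep(inv, each = m)
  ym <- xh * rep(p$gamma, each = m) + rep(p$beta, each = m)
  dim(ym) <- c(S, N, C)
  y <- aperm(ym, c(1L, 3L, 2L)); dim(y) <- d
  list(y = y, cache = list(xh = xh, inv = inv, gamma = p$gamma,
                           dims = d, S = S, C = C, N = N))
}

bn_bw <- function(dy, cache) {
  d <- cache$dims; S <- cache$S; C <- cache$C; N <- cache$N
  m <- S * N
  dyr <- dy; dim(dyr) <- c(S, C, N)
  dym <- aperm(dyr, c(1L, 3L, 2L)); dim(dym) <- c(m, C)
  dgamma <- colSums(dym * cache$xh)
  dbeta <- colSums(dym)
  dxh <- dym * rep(cache$gamma, each = m)
  t1 <- colSums(dxh) / m
  t2 <- colSums(dxh * cache$xh) / m
  dxm <- rep(cache$inv, each = m) *
    (dxh - rep(t1, each = m) - cache$xh * rep(t2, each = m))
  dim(dxm) <- c(S, N, C)
  dx <- aperm(dxm, c(1L, 3L, 2L)); dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- dense / activations / dropout ----------------------------------------

dense_fw <- function(x, W, b) {
  list(y = W %*% x + b, cache = list(x = x, W = W))
}

dense_bw <- function(dy, cache) {
  list(dx = crossprod(cache$W, dy),
       dW = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

relu_fw <- function(x) {
  y <- x; y[y < 0] <- 0
  list(y = y, cache = x > 0)
}

relu_bw <- function(dy, cache) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

dropout_fw <- function(x, rate, training = FALSE) {
  if (!training || rate <= 0)
    return(list(y = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(y = x * mask, cache = mask)
}

dropout_bw <- function(dy, cache) if (is.null(cache)) dy else dy * cache

# Global average pooling over all leading (spatial/temporal) dimensions.
gap_fw <- function(x) {
  d <- dim(x); nd <- length(d)
  S <- prod(d[-c(nd - 1L, nd)])
  xm <- x; dim(xm) <- c(S, d[nd - 1L] * d[nd])
  y <- matrix(colMeans(xm), d[nd - 1L], d[nd])
  list(y = y, cache = list(dims = d, S = S))
}

gap_bw <- function(dy, cache) {
  d <- cache$dims
  dx <- rep(as.vector(dy) / cache$S, each = cache$S)
  dim(dx) <- d
  dx
}

# ---- parameter initialisation ----------------------------------------------

he_conv1d <- function(k, Cin, Fo) {
  list(W = array(stats::rnorm(k * Cin * Fo, sd = sqrt(2 / (k * Cin))),
                 c(k, Cin, Fo)),
       b = numeric(Fo))
}

he_conv2d <- function(kh, kw, Cin, Fo) {
  list(W = array(stats::rnorm(kh * kw * Cin * Fo,
                              sd = sqrt(2 / (kh * kw * Cin))),
                 c(kh, kw, Cin, Fo)),
       b = numeric(Fo))
}

he_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_out * n_in, sd = sqrt(2 / n_in)),
                  n_out, n_in),
       b = numeric(n_out))
}
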