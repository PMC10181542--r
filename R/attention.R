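# Attention gates. Internal functions operate on batched layouts
# ((T, C, N) / (H, W, C, N)); the exported operations take the conventional
# single-sample channel-first shapes (C x T and C x H x W).

#' Attention parameter set
#'
#' Squeeze/excite affine weights shared by the channel-attention gates, plus
#' the spatial convolution kernel used by the spatial gate. The excitation
#' bottleneck width is `max(1, floor(channels / r))`.
#'
#' @param channels Number of feature channels `C` gated by the module.
#' @param r Reduction ratio of the excitation bottleneck (default 16, the
#'   SE-block convention).
#' @param k Spatial convolution kernel size (odd; default 7, the CBAM
#'   convention).
#' @param init `"he"` for random He-scaled weights, `"zero"` for all-zero
#'   weights (useful for hand computation: zero weights give 0.5 gates).
#' @return Object of class `attention_params`.
#' @export
attention_params <- function(channels, r = 16L, k = 7L,
                             init = c("he", "zero")) {
  init <- match.arg(init)
  if (k %% 2L == 0L) stopf("spatial kernel size must be odd, got %d", k)
  cr <- max(1L, channels %/% r)
  p <- if (init == "zero") {
    list(W1 = matrix(0, cr, channels), b1 = numeric(cr),
         W2 = matrix(0, channels, cr), b2 = numeric(channels),
         conv = list(W = array(0, c(k, k, 2L, 1L)), b = 0))
  } else {
    cv <- he_conv2d(k, k, 2L, 1L)
    list(W1 = he_dense(channels, cr)$W, b1 = numeric(cr),
         W2 = he_dense(cr, channels)$W, b2 = numeric(channels),
         conv = cv)
  }
  structure(c(p, list(channels = channels, r = r, k = k)),
            class = "attention_params")
}

check_att <- function(p, C) {
  if (!inherits(p, "attention_params")) stopf("p must be attention_params")
  if (p$channels != C)
    stopf("attention parameters built for %d channels, feature map has %d",
          p$channels, C)
}

# Shared excitation MLP: e(s) = W2 relu(W1 s + b1) + b2, s is (C, N).
excite_fw <- function(s, p) {
  z1 <- p$W1 %*% s + p$b1
  a1 <- z1; a1[a1 < 0] <- 0
  list(e = p$W2 %*% a1 + p$b2, z1 = z1, a1 = a1, s = s)
}

excite_bw <- function(de, cache, p) {
  dW2 <- tcrossprod(de, cache$a1)
  db2 <- rowSums(de)
  da1 <- crossprod(p$W2, de)
  dz1 <- da1 * (cache$z1 > 0)
  dW1 <- tcrossprod(dz1, cache$s)
  db1 <- rowSums(dz1)
  list(ds = crossprod(p$W1, dz1), dW1 = dW1, db1 = db1,
       dW2 = dW2, db2 = db2)
}

# ---- 1D channel attention (squeeze-and-excite, average pool) ---------------

ca1d_fw <- function(x, p) {
  d <- dim(x)                                   # (T, C, N)
  xm <- x; dim(xm) <- c(d[1], d[2] * d[3])
  s <- matrix(colMeans(xm), d[2], d[3])
  ex <- excite_fw(s, p)
  g <- sigmoid(ex$e)                            # (C, N)
  y <- x * rep(as.vector(g), each = d[1])
  dim(y) <- d
  list(y = y, cache = list(x = x, g = g, ex = ex, dims = d))
}

ca1d_bw <- function(dy, cache, p) {
  d <- cache$dims
  gbig <- rep(as.vector(cache$g), each = d[1])
  dx <- dy * gbig
  dgm <- dy * cache$x; dim(dgm) <- c(d[1], d[2] * d[3])
  dg <- matrix(colSums(dgm), d[2], d[3])
  de <- dg * cache$g * (1 - cache$g)
  eb <- excite_bw(de, cache$ex, p)
  dx <- dx + rep(as.vector(eb$ds) / d[1], each = d[1])
  dim(dx) <- d
  list(dx = dx, dW1 = eb$dW1, db1 = eb$db1, dW2 = eb$dW2, db2 = eb$db2)
}

# ---- 2D hybrid channel attention (max + avg pooled, shared excitation) -----

hca2d_fw <- function(x, p) {
  d <- dim(x)                                   # (H, W, C, N)
  hw <- d[1] * d[2]
  xm <- x; dim(xm) <- c(hw, d[3] * d[4])
  s_avg <- matrix(colMeans(xm), d[3], d[4])
  am <- max.col(t(xm), ties.method = "first")
  s_max <- matrix(xm[cbind(am, seq_along(am))], d[3], d[4])
  ex_a <- excite_fw(s_avg, p)
  ex_m <- excite_fw(s_max, p)
  g <- sigmoid(ex_m$e + ex_a$e)                 # (C, N)
  y <- x * rep(as.vector(g), each = hw)
  dim(y) <- d
  list(y = y, cache = list(x = x, g = g, ex_a = ex_a, ex_m = ex_m,
                           am = am, dims = d))
}

hca2d_bw <- function(dy, cache, p) {
  d <- cache$dims; hw <- d[1] * d[2]
  dx <- dy * rep(as.vector(cache$g), each = hw)
  dgm <- dy * cache$x; dim(dgm) <- c(hw, d[3] * d[4])
  dg <- matrix(colSums(dgm), d[3], d[4])
  de <- dg * cache$g * (1 - cache$g)
  eb_a <- excite_bw(de, cache$ex_a, p)
  eb_m <- excite_bw(de, cache$ex_m, p)
  dxm <- matrix(0, hw, d[3] * d[4])
  dxm[cbind(cache$am, seq_along(cache$am))] <- as.vector(eb_m$ds)
  dx <- dx + rep(as.vector(eb_a$ds) / hw, each = hw) + as.vector(dxm)
  dim(dx) <- d
  list(dx = dx,
       dW1 = eb_a$dW1 + eb_m$dW1, db1 = eb_a$db1 + eb_m$db1,
       dW2 = eb_a$dW2 + eb_m$dW2, db2 = eb_a$db2 + eb_m$db2)
}

# ---- 2D spatial attention (channel max/mean maps -> conv -> sigmoid) -------

hsa2d_fw <- function(x, p) {
  d <- dim(x)                                   # (H, W, C, N)
  hw <- d[1] * d[2]
  xr <- x; dim(xr) <- c(hw, d[3], d[4])
  xq <- aperm(xr, c(1L, 3L, 2L)); dim(xq) <- c(hw * d[4], d[3])
  t2 <- rowMeans(xq)                            # channel mean, (hw*N)
  t1 <- xq[, 1L]; amc <- rep(1L, length(t1))    # channel max with argmax
  if (d[3] > 1L) for (cchan in 2:d[3]) {
    v <- xq[, cchan]
    upd <- v > t1
    t1[upd] <- v[upd]; amc[upd] <- cchan
  }
  t3 <- array(0, c(d[1], d[2], 2L, d[4]))
  t3[, , 1L, ] <- array(t1, c(hw, d[4]))
  t3[, , 2L, ] <- array(t2, c(hw, d[4]))
  cv <- conv2d_fw(t3, p$conv$W, p$conv$b, stride = 1L,
                  pad = (p$k - 1L) %/% 2L)
  z <- cv$y                                     # (H, W, 1, N)
  g <- sigmoid(as.vector(z)); dim(g) <- c(hw, d[4])
  garr <- aperm(array(as.vector(g), c(hw, d[4], d[3])), c(1L, 3L, 2L))
  y <- as.vector(xr) * as.vector(garr)
  dim(y) <- d
  list(y = y, cache = list(x = x, g = g, garr = garr, amc = amc,
                           cv_cache = cv$cache, dims = d))
}

hsa2d_bw <- function(dy, cache, p) {
  d <- cache$dims; hw <- d[1] * d[2]
  dx <- as.vector(dy) * as.vector(cache$garr)
  dyr <- dy; dim(dyr) <- c(hw, d[3], d[4])
  xr <- cache$x; dim(xr) <- c(hw, d[3], d[4])
  prod_ <- dyr * xr
  pq <- aperm(prod_, c(1L, 3L, 2L)); dim(pq) <- c(hw * d[4], d[3])
  dg <- rowSums(pq)                             # (hw*N)
  gv <- as.vector(cache$g)
  dz <- dg * gv * (1 - gv)
  dim(dz) <- c(d[1], d[2], 1L, d[4])
  cb <- conv2d_bw(dz, cache$cv_cache)
  dT3 <- cb$dx                                  # (H, W, 2, N)
  dT1 <- as.vector(dT3[, , 1L, ]); dT2 <- as.vector(dT3[, , 2L, ])
  # spread mean gradient over channels; scatter max gradient to argmax channel
  dq <- matrix(dT2 / d[3], hw * d[4], d[3])
  dq[cbind(seq_along(cache$amc), cache$amc)] <-
    dq[cbind(seq_along(cache$amc), cache$amc)] + dT1
  dim(dq) <- c(hw, d[4], d[3])
  dxq <- aperm(dq, c(1L, 3L, 2L))
  dx <- dx + as.vector(dxq)
  dim(dx) <- d
  list(dx = dx, dconv_W = cb$dW, dconv_b = cb$db)
}

# ---- exported single-sample operations -------------------------------------

#' 1D channel attention gate
#'
#' Squeeze-and-excite channel gate for 1D feature maps: the channel-wise
#' global average is passed through a two-layer bottleneck
#' (`sigmoid(W2 relu(W1 s + b1) + b2)`) and the resulting per-channel gate in
#' (0,1) rescales the input.
#'
#' @param F_map Numeric `C x T` matrix (channels by time).
#' @param p [attention_params()] built for `C` channels.
#' @return Gated `C x T` matrix.
#' @export
ca_1d <- function(F_map, p) {
  assert_finite_matrix(F_map, "F_map")
  check_att(p, nrow(F_map))
  x <- array(t(F_map), c(ncol(F_map), nrow(F_map), 1L))
  t(ca1d_fw(x, p)$y[, , 1L])
}

#' 2D hybrid channel attention gate
#'
#' Channel gate with two pooling branches: global max and global average
#' pooled channel vectors pass through one shared excitation bottleneck; the
#' two excitations are summed and squashed
#' (`gate = sigmoid(e(maxpool) + e(avgpool))`) before rescaling each channel.
#'
#' @param F_map Numeric `C x H x W` array.
#' @param p [attention_params()] built for `C` channels.
#' @return Gated `C x H x W` array.
#' @export
hca_2d <- function(F_map, p) {
  stopifnot(is.array(F_map), length(dim(F_map)) == 3L)
  check_att(p, dim(F_map)[1])
  x <- aperm(F_map, c(2L, 3L, 1L))
  dim(x) <- c(dim(x), 1L)
  y <- hca2d_fw(x, p)$y
  dim(y) <- dim(y)[1:3]
  aperm(y, c(3L, 1L, 2L))
}

#' 2D spatial attention gate
#'
#' Spatial gate: channel-wise max and mean maps are stacked into a 2-channel
#' image, convolved with a `k x k` kernel (size-preserving padding) and
#' squashed with a sigmoid; the resulting `H x W` gate rescales every
#' channel.
#'
#' @param F_map Numeric `C x H x W` array.
#' @param p [attention_params()] (uses the `conv` kernel; `k` must be odd).
#' @return Gated `C x H x W` array.
#' @export
hsa_2d <- function(F_map, p) {
  stopifnot(is.array(F_map), length(dim(F_map)) == 3L)
  if (!inherits(p, "attention_params")) stopf("p must be attention_params")
  x <- aperm(F_map, c(2L, 3L, 1L))
  dim(x) <- c(dim(x), 1L)
  y <- hsa2d_fw(x, p)$y
  dim(y) <- dim(y)[1:3]
  aperm(y, c(3L, 1L, 2L))
}

#' Serial hybrid attention (channel gate then spatial gate)
#'
#' @param F_map Numeric `C x H x W` array.
#' @param p [attention_params()].
#' @return `hsa_2d(hca_2d(F_map, p), p)`.
#' @export
ha_2d <- function(F_map, p) hsa_2d(hca_2d(F_map, p), p)
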