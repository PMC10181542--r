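# Periodized orthogonal discrete wavelet transform, used by the denoiser.
# Analysis is the correlation form A[i] = sum_k h[k] x[2(i-1)+k-1 mod n],
# synthesis the matching scatter; perfect reconstruction holds for any
# orthonormal filter pair and even length (verified by a round-trip test).

# db6 scaling (reconstruction low-pass) coefficients, sum = sqrt(2).
DB6_H <- c(0.111540743350109, 0.494623890398453, 0.751133908021095,
           0.315250351709198, -0.226264693965440, -0.129766867567262,
           0.097501605587322, 0.027522865530305, -0.031582039318486,
           0.000553842201161, 0.004777257511011, -0.001077301085308)

wt_filters <- function(wavelet = "db6") {
  h <- switch(wavelet,
              db6 = DB6_H,
              haar = c(1, 1) / sqrt(2),
              stopf("unknown wavelet '%s'", wavelet))
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)
  list(h = h, g = g, L = L)
}

dwt_step <- function(x, flt) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  idx <- (outer(seq(0L, n - 2L, by = 2L), seq_len(flt$L) - 1L, "+") %% n) + 1L
  xw <- matrix(x[idx], nrow = n %/% 2L)
  list(a = as.vector(xw %*% flt$h), d = as.vector(xw %*% flt$g))
}

idwt_step <- function(a, d, flt) {
  n2 <- length(a)
  n <- 2L * n2
  out <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (k in seq_len(flt$L)) {
    p <- ((base + k - 1L) %% n) + 1L
    out[p] <- out[p] + flt$h[k] * a + flt$g[k] * d
  }
  out
}

# Full decomposition to `levels`; returns list(a = coarsest, d = list of
# detail vectors, finest first).
dwt_periodized <- function(x, levels, wavelet = "db6") {
  flt <- wt_filters(wavelet)
  d <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, flt)
    a <- s$a
    d[[j]] <- s$d
  }
  list(a = a, d = d, wavelet = wavelet)
}

idwt_periodized <- function(dec) {
  flt <- wt_filters(dec$wavelet)
  a <- dec$a
  for (j in rev(seq_along(dec$d))) a <- idwt_step(a, dec$d[[j]], flt)
  a
}
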