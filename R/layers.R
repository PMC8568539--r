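# Differentiable layer primitives. Every *_fwd returns list(y, cache) and
# the matching *_bwd maps the upstream gradient back onto inputs and
# parameters. Feature maps are (H, W, C, N) double arrays.

conv_fwd <- function(x, w, b, pad) {
  list(y = .conv2d_fwd(x, w, b, as.integer(pad)),
       cache = list(x = x, w = w, pad = as.integer(pad)))
}

conv_bwd <- function(dy, cache) {
  .conv2d_bwd(cache$x, cache$w, dy, cache$pad)
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batch normalization over (H, W, N) per channel. Training mode uses batch
# statistics (population variance) and updates running averages.
bn_fwd <- function(x, gamma, beta, state, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  C <- d[3]
  xp <- aperm(x, c(1, 2, 4, 3))
  Xm <- matrix(xp, ncol = C)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm * Xm) - mu * mu
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * v
  } else {
    mu <- state$rm
    v <- state$rv
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(Xm, 2, mu, "-")
  xhat <- sweep(xhat, 2, invstd, "*")
  Ym <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  y <- aperm(array(Ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                           training = training),
       state = state)
}

bn_bwd <- function(dy, cache) {
  d <- cache$d
  C <- d[3]
  dYm <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  m <- nrow(dYm)
  dgamma <- colSums(dYm * xhat)
  dbeta <- colSums(dYm)
  dxhat <- sweep(dYm, 2, cache$gamma, "*")
  if (cache$training) {
    t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dXm <- sweep(t1 - t2, 2, cache$invstd, "*")
  } else {
    dXm <- sweep(dxhat, 2, cache$invstd, "*")
  }
  dx <- aperm(array(dXm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(x) {
  r <- .maxpool2_fwd(x)
  list(y = r$y, cache = list(idx = r$idx, d = dim(x)))
}
pool_bwd <- function(dy, cache) .maxpool2_bwd(dy, cache$idx, cache$d)

upconv_fwd <- function(x, w, b) {
  list(y = .upconv2_fwd(x, w, b), cache = list(x = x, w = w))
}
upconv_bwd <- function(dy, cache) .upconv2_bwd(cache$x, cache$w, dy)

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

# Global average pooling to a (C, N) matrix.
gap_fwd <- function(x) {
  d <- dim(x)
  g <- matrix(0, d[3], d[4])
  hw <- d[1] * d[2]
  for (n in seq_len(d[4]))
    g[, n] <- colSums(matrix(x[, , , n], hw, d[3]))
  g / hw
}

#' Dual attention gate
#'
#' Computes the attention-weighted sum `Q(F) * F + P(F) * F` where `Q` is a
#' single-channel spatial attention mask (1x1 convolution over channels +
#' sigmoid, one weight per position) and `P` is a per-channel attention
#' code (global average pooling + 1x1 convolution + sigmoid, one weight
#' per channel). `Q` broadcasts over channels and `P` over positions, so
#' the output shape equals the input shape.
#'
#' @param f feature map, (H, W, C, N) array (a matrix or (H, W, C) array
#'   is promoted)
#' @param params list with `q.w` (1,1,C,1), `q.b` (1), `p.w` (C,C) and
#'   `p.b` (C)
#' @return list with `y` (same shape as `f`), the gates `q` and `p`, and
#'   a `cache` for the backward pass
#' @export
dual_attention <- function(f, params) {
  f <- as_feature_map(f)
  d <- dim(f)
  C <- d[3]
  zq <- .conv2d_fwd(f, params$q.w, params$q.b, 0L)
  q <- sigmoid(zq)                                  # (H, W, 1, N)
  g <- gap_fwd(f)                                   # (C, N)
  zp <- t(params$p.w) %*% g + params$p.b
  p <- sigmoid(zp)                                  # (C, N)
  qb <- q[, , rep(1L, C), , drop = FALSE]
  pb <- array(rep(as.vector(p), each = d[1] * d[2]), dim = d)
  s <- qb + pb
  list(y = s * f, q = q, p = p,
       cache = list(f = f, q = q, p = p, s = s, g = g, params = params, d = d))
}

dual_attention_bwd <- function(dy, cache) {
  d <- cache$d
  C <- d[3]
  hw <- d[1] * d[2]
  df <- dy * cache$s
  ds <- dy * cache$f
  dq <- array(0, c(d[1], d[2], 1, d[4]))
  dp <- matrix(0, C, d[4])
  for (n in seq_len(d[4])) {
    m <- matrix(ds[, , , n], hw, C)
    dq[, , 1, n] <- rowSums(m)
    dp[, n] <- colSums(m)
  }
  dzq <- dq * cache$q * (1 - cache$q)
  cq <- conv_bwd(dzq, list(x = cache$f, w = cache$params$q.w, pad = 0L))
  dzp <- dp * cache$p * (1 - cache$p)
  dwp <- cache$g %*% t(dzp)
  dbp <- rowSums(dzp)
  dg <- cache$params$p.w %*% dzp
  dgap <- array(rep(as.vector(dg) / hw, each = hw), dim = d)
  list(dx = df + cq$dx + dgap,
       dq.w = cq$dw, dq.b = cq$db, dp.w = dwp, dp.b = dbp)
}

as_feature_map <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("expected a (H, W, C, N) feature map")
  x
}

softmax_ch <- function(z) {
  # softmax over the channel dimension (dim 3)
  d <- dim(z)
  zm <- pmax(z[, , 1, , drop = FALSE], z[, , 2, , drop = FALSE])
  if (d[3] != 2) {
    m <- apply(z, c(1, 2, 4), max)
    dim(m) <- c(d[1], d[2], 1, d[4])
    zm <- m
  }
  e <- exp(z - zm[, , rep(1L, d[3]), , drop = FALSE])
  tot <- e[, , 1, , drop = FALSE]
  for (c in seq_len(d[3])[-1]) tot <- tot + e[, , c, , drop = FALSE]
  e / tot[, , rep(1L, d[3]), , drop = FALSE]
}
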