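# Layer primitives for the segmentation network. Tensors are R arrays of
# dim (H, W, C, N). Every *_fw returns list(y, cache); every *_bw takes
# (cache, gy) and returns list(gx, and parameter gradients where relevant).
# Backprop is hand-written; the heavy kernels live in src/calcseg_ops.cpp.

# broadcast a per-channel vector over (H, W, ., N)
bc_ch <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

init_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  list(w = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout))
}

conv_fw <- function(x, p, kh = 3, kw = 3, stride = 1, pad = 1) {
  y <- cpp_conv2d_fw(x, p$w, p$b, kh, kw, stride, pad)
  list(y = y, cache = list(x = x, kh = kh, kw = kw, stride = stride,
                           pad = pad))
}

conv_bw <- function(p, cache, gy) {
  cpp_conv2d_bw(cache$x, p$w, gy, cache$kh, cache$kw, cache$stride,
                cache$pad)
}

init_dwconv <- function(c) {
  list(w = matrix(rnorm(9 * c, sd = sqrt(2 / 9)), 9, c), b = numeric(c))
}

dwconv_fw <- function(x, p) {
  list(y = cpp_dwconv_fw(x, p$w, p$b), cache = list(x = x))
}

dwconv_bw <- function(p, cache, gy) cpp_dwconv_bw(cache$x, p$w, gy)

init_convt <- function(cin, cout) {
  fan_in <- cin
  list(w = array(rnorm(cin * cout * 4, sd = sqrt(2 / fan_in)),
                 dim = c(cin, cout, 2, 2)),
       b = numeric(cout))
}

convt_fw <- function(x, p) {
  cout <- dim(p$w)[2]
  list(y = cpp_convt2_fw(x, p$w, p$b, cout), cache = list(x = x))
}

convt_bw <- function(p, cache, gy) {
  cpp_convt2_bw(cache$x, p$w, gy, dim(p$w)[2])
}

maxpool_fw <- function(x) {
  r <- cpp_maxpool2_fw(x)
  list(y = r$y, cache = list(idx = r$idx, H = dim(x)[1], W = dim(x)[2]))
}

maxpool_bw <- function(cache, gy) cpp_maxpool2_bw(cache$idx, gy, cache$H,
                                                  cache$W)

relu_fw <- function(x) list(y = pmax(x, 0), cache = list(pos = x > 0))
relu_bw <- function(cache, gy) gy * cache$pos

silu_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(x = x, s = s))
}
silu_bw <- function(cache, gy) {
  s <- cache$s
  gy * (s * (1 + cache$x * (1 - s)))
}

gelu_fw <- function(x) {
  # tanh approximation; backward uses the matching derivative
  k <- sqrt(2 / pi)
  inner <- k * (x + 0.044715 * x^3)
  t <- tanh(inner)
  list(y = 0.5 * x * (1 + t), cache = list(x = x, t = t, k = k))
}
gelu_bw <- function(cache, gy) {
  x <- cache$x; t <- cache$t; k <- cache$k
  dinner <- k * (1 + 3 * 0.044715 * x^2)
  gy * (0.5 * (1 + t) + 0.5 * x * (1 - t^2) * dinner)
}

sigmoid_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = s, cache = list(s = s))
}
sigmoid_bw <- function(cache, gy) gy * cache$s * (1 - cache$s)

init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       rm = numeric(c), rv = rep(1, c))
}

bn_fw <- function(x, p, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (training) {
    st <- cpp_channel_stats(x)
    mu <- st$sum / m
    va <- pmax(st$sumsq / m - mu^2, 0)
    upd <- list(rm = (1 - momentum) * p$rm + momentum * mu,
                rv = (1 - momentum) * p$rv + momentum * va)
  } else {
    mu <- p$rm; va <- p$rv
    upd <- NULL
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- cpp_scale_shift(x, inv, -mu * inv)
  y <- cpp_scale_shift(xhat, p$gamma, p$beta)
  list(y = y, cache = list(xhat = xhat, inv = inv, d = d), update = upd)
}

bn_bw <- function(p, cache, gy) {
  cpp_bn_bw(gy, cache$xhat, p$gamma, cache$inv)
}

init_ln <- function(c) list(gamma = rep(1, c), beta = numeric(c))

# layer norm across channels at each spatial position and sample
ln_fw <- function(x, p, eps = 1e-5) {
  d <- dim(x)
  C <- d[3]
  xp <- aperm(x, c(1, 2, 4, 3))          # (H, W, N, C)
  mu <- rowMeans(xp, dims = 3)
  va <- rowMeans(xp^2, dims = 3) - mu^2
  inv <- 1 / sqrt(pmax(va, 0) + eps)
  xhat <- aperm((xp - as.vector(mu)) * as.vector(inv), c(1, 2, 4, 3))
  y <- xhat * bc_ch(p$gamma, d) + bc_ch(p$beta, d)
  list(y = y, cache = list(xhat = xhat, inv = inv, d = d))
}

ln_bw <- function(p, cache, gy) {
  d <- cache$d
  C <- d[3]
  xhat <- cache$xhat
  gym <- matrix(aperm(gy, c(1, 2, 4, 3)), ncol = C)
  xhatm <- matrix(aperm(xhat, c(1, 2, 4, 3)), ncol = C)
  ggamma <- colSums(gym * xhatm)
  gbeta <- colSums(gym)
  gxhat <- gy * bc_ch(p$gamma, d)
  gp <- aperm(gxhat, c(1, 2, 4, 3))      # (H, W, N, C)
  xp <- aperm(xhat, c(1, 2, 4, 3))
  s1 <- rowMeans(gp, dims = 3)
  s2 <- rowMeans(gp * xp, dims = 3)
  gx <- (gp - as.vector(s1) - xp * as.vector(s2)) * as.vector(cache$inv)
  list(gx = aperm(gx, c(1, 2, 4, 3)), ggamma = ggamma, gbeta = gbeta)
}

init_se <- function(c, reduction = 4) {
  h <- max(1L, c %/% reduction)
  list(w1 = matrix(rnorm(c * h, sd = sqrt(2 / c)), c, h), b1 = numeric(h),
       w2 = matrix(rnorm(h * c, sd = sqrt(2 / h)), h, c), b2 = numeric(c))
}

se_fw <- function(x, p) {
  d <- dim(x)
  C <- d[3]; N <- d[4]
  s <- t(vapply(seq_len(N), function(n)
    colMeans(matrix(x[, , , n], ncol = C)), numeric(C)))  # N x C
  z1 <- s %*% p$w1
  z1 <- sweep(z1, 2, p$b1, "+")
  a1 <- pmax(z1, 0)
  z2 <- a1 %*% p$w2
  z2 <- sweep(z2, 2, p$b2, "+")
  g <- 1 / (1 + exp(-z2))                                  # N x C gates
  gate <- array(rep(as.vector(t(g)), each = d[1] * d[2]), dim = d)
  list(y = x * gate, cache = list(x = x, s = s, a1 = a1, g = g, d = d,
                                  gate = gate))
}

se_bw <- function(p, cache, gy) {
  d <- cache$d
  C <- d[3]; N <- d[4]
  gx_direct <- gy * cache$gate
  # gradient into the gates: sum over spatial of gy * x
  gg <- t(vapply(seq_len(N), function(n)
    colSums(matrix((gy * cache$x)[, , , n], ncol = C)), numeric(C)))
  gz2 <- gg * cache$g * (1 - cache$g)                      # N x C
  gw2 <- t(cache$a1) %*% gz2
  gb2 <- colSums(gz2)
  ga1 <- gz2 %*% t(p$w2)
  gz1 <- ga1 * (cache$a1 > 0)
  gw1 <- t(cache$s) %*% gz1
  gb1 <- colSums(gz1)
  gs <- gz1 %*% t(p$w1)                                    # N x C
  m <- d[1] * d[2]
  gx_pool <- array(rep(as.vector(t(gs)) / m, each = m), dim = d)
  list(gx = gx_direct + gx_pool, gw1 = gw1, gb1 = gb1, gw2 = gw2, gb2 = gb2)
}

# spatial shift of channel groups, UNeXt-style: channels are split into
# `size` groups shifted by -floor(size/2) .. +floor(size/2) along one axis
shift_fw <- function(x, axis, size = 5) {
  d <- dim(x)
  C <- d[3]
  offs <- seq_len(size) - 1L - size %/% 2L
  grp <- rep(seq_len(size), length.out = C)
  y <- array(0, d)
  for (g in seq_len(size)) {
    ch <- which(grp == g)
    if (!length(ch)) next
    y[, , ch, ] <- shift_axis(x[, , ch, , drop = FALSE], axis, offs[g])
  }
  list(y = y, cache = list(axis = axis, size = size, d = d))
}

shift_bw <- function(cache, gy) {
  size <- cache$size
  C <- cache$d[3]
  offs <- seq_len(size) - 1L - size %/% 2L
  grp <- rep(seq_len(size), length.out = C)
  gx <- array(0, cache$d)
  for (g in seq_len(size)) {
    ch <- which(grp == g)
    if (!length(ch)) next
    gx[, , ch, ] <- shift_axis(gy[, , ch, , drop = FALSE], cache$axis,
                               -offs[g])
  }
  gx
}

shift_axis <- function(x, axis, off) {
  if (off == 0) return(x)
  d <- dim(x)
  y <- array(0, d)
  n <- d[axis]
  src <- seq_len(n) - off
  ok <- src >= 1 & src <= n
  if (!any(ok)) return(y)
  if (axis == 1) y[which(ok), , , ] <- x[src[ok], , , , drop = FALSE]
  else y[, which(ok), , ] <- x[, src[ok], , , drop = FALSE]
  y
}
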