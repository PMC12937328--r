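# Internal neural-network primitives. Features live in channel-major
# matrices [C x M] where M enumerates elements (points, grouped neighbors or
# batch samples) column-wise, so that pointwise (kernel-size-1) convolutions
# are plain BLAS matrix products. Every forward has a matching analytic
# backward; correctness is checked against finite differences in the tests.

nn_linear_init <- function(cin, cout) {
  # He-style initialisation for ReLU networks.
  list(W = matrix(stats::rnorm(cout * cin, sd = sqrt(2 / cin)), cout, cin),
       b = numeric(cout))
}

nn_linear_fwd <- function(p, x) p$W %*% x + p$b

nn_linear_bwd <- function(p, x, dy) {
  list(dx = crossprod(p$W, dy),
       dW = tcrossprod(dy, x),
       db = .rowSums(dy, nrow(dy), ncol(dy)))
}

# Partial pointwise convolution: only the first cp = ceiling(ratio * C)
# channels are convolved (cp -> cp); the remaining channels are copied
# bit-identically. With ratio = 1 this is an ordinary full convolution.
nn_pconv_init <- function(C, ratio) {
  cp <- as.integer(ceiling(C * ratio))
  if (cp < 1L) stopf("partial channel count must be >= 1")
  p <- nn_linear_init(cp, cp)
  p$cp <- cp
  p
}

nn_pconv_fwd <- function(p, x) {
  cp <- p$cp
  if (cp == nrow(x)) return(nn_linear_fwd(p, x))
  y <- x
  y[seq_len(cp), ] <- p$W %*% x[seq_len(cp), , drop = FALSE] + p$b
  y
}

nn_pconv_bwd <- function(p, x, dy) {
  cp <- p$cp
  if (cp == nrow(x)) return(nn_linear_bwd(p, x, dy))
  act <- seq_len(cp)
  dx <- dy
  dtop <- dy[act, , drop = FALSE]
  dx[act, ] <- crossprod(p$W, dtop)
  list(dx = dx,
       dW = tcrossprod(dtop, x[act, , drop = FALSE]),
       db = rowSums(dtop))
}

nn_bn_init <- function(C) {
  list(g = rep(1, C), b = numeric(C))
}

nn_bn_buf_init <- function(C) {
  list(rm = numeric(C), rv = rep(1, C))
}

# Batch normalisation across the element dimension, per channel.
# In training mode batch statistics are used and running statistics updated
# (momentum 0.1, unbiased running variance); in eval mode running statistics
# are used, so the output of one sample never depends on its batch mates.
# The fused forward/backward passes live in compiled code.
nn_bn_fwd <- function(p, buf, x, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    n <- ncol(x)
    r <- bn_train_fwd_cpp(x, p$g, p$b, eps)
    vu <- if (n > 1L) r$v * n / (n - 1) else r$v
    newbuf <- list(rm = (1 - momentum) * buf$rm + momentum * r$mu,
                   rv = (1 - momentum) * buf$rv + momentum * vu)
    list(y = r$y, buf = newbuf, cache = list(xhat = r$xhat, inv = r$inv, n = n))
  } else {
    y <- bn_eval_fwd_cpp(x, p$g, p$b, buf$rm, buf$rv, eps)
    list(y = y, buf = buf,
         cache = list(inv = 1 / sqrt(buf$rv + eps), x = x, rm = buf$rm))
  }
}

nn_bn_bwd <- function(p, cache, dy, train) {
  if (train) {
    r <- bn_train_bwd_cpp(dy, cache$xhat, cache$inv, p$g)
    list(dx = r$dx, dg = r$dg, db = r$db)
  } else {
    xhat <- (cache$x - cache$rm) * cache$inv
    C <- nrow(dy); n <- ncol(dy)
    list(dx = dy * p$g * cache$inv,
         dg = .rowSums(dy * xhat, C, n),
         db = .rowSums(dy, C, n))
  }
}

nn_relu_fwd <- function(x) relu_fwd_cpp(x)

nn_relu_bwd <- function(mask, dy) dy * mask

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# Residual block: y = relu(x + bn2(conv2(relu(bn1(conv1(x)))))).
# `partial_ratio = NULL` gives a conventional full-convolution block;
# otherwise both convolutions are partial (cp -> cp on the leading channels).
resblock_init <- function(C, partial_ratio = NULL) {
  conv_init <- if (is.null(partial_ratio)) function() nn_linear_init(C, C)
               else function() nn_pconv_init(C, partial_ratio)
  list(par = list(c1 = conv_init(), bn1 = nn_bn_init(C),
                  c2 = conv_init(), bn2 = nn_bn_init(C)),
       buf = list(bn1 = nn_bn_buf_init(C), bn2 = nn_bn_buf_init(C)),
       partial = !is.null(partial_ratio))
}

resblock_fwd <- function(par, buf, x, train, partial) {
  cf <- if (partial) nn_pconv_fwd else nn_linear_fwd
  h1 <- cf(par$c1, x)
  b1 <- nn_bn_fwd(par$bn1, buf$bn1, h1, train)
  r1 <- nn_relu_fwd(b1$y)
  h2 <- cf(par$c2, r1$y)
  b2 <- nn_bn_fwd(par$bn2, buf$bn2, h2, train)
  s <- x + b2$y
  r2 <- nn_relu_fwd(s)
  list(y = r2$y,
       buf = list(bn1 = b1$buf, bn2 = b2$buf),
       cache = list(x = x, bn1 = b1$cache, m1 = r1$mask, r1y = r1$y,
                    bn2 = b2$cache, m2 = r2$mask))
}

resblock_bwd <- function(par, cache, dy, train, partial) {
  cb <- if (partial) nn_pconv_bwd else nn_linear_bwd
  ds <- nn_relu_bwd(cache$m2, dy)
  g2 <- nn_bn_bwd(par$bn2, cache$bn2, ds, train)
  gc2 <- cb(par$c2, cache$r1y, g2$dx)
  dr1 <- nn_relu_bwd(cache$m1, gc2$dx)
  g1 <- nn_bn_bwd(par$bn1, cache$bn1, dr1, train)
  gc1 <- cb(par$c1, cache$x, g1$dx)
  list(dx = ds + gc1$dx,
       grads = list(c1 = list(W = gc1$dW, b = gc1$db),
                    bn1 = list(g = g1$dg, b = g1$db),
                    c2 = list(W = gc2$dW, b = gc2$db),
                    bn2 = list(g = g2$dg, b = g2$db)))
}

se_init <- function(C, reduction) {
  hidden <- max(1L, C %/% reduction)
  if (C < reduction)
    warnf("SE hidden width clamped to 1 (channels %d < reduction %d)", C, reduction)
  list(fc1 = nn_linear_init(C, hidden), fc2 = nn_linear_init(hidden, C))
}

# Squeeze-and-excitation over per-sample center points. x is [C x (B*S)]
# with the S columns of each sample contiguous; squeeze = per-sample mean,
# excitation = sigmoid(FC2(relu(FC1(z)))), rescale = channel-wise gating.
se_fwd <- function(par, x, B, S) {
  C <- nrow(x)
  z <- matrix(0, C, B)
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * S + 1L):(b * S)
    z[, b] <- rowMeans(x[, cols, drop = FALSE])
  }
  h_pre <- nn_linear_fwd(par$fc1, z)
  hm <- h_pre > 0
  h <- h_pre * hm
  gpre <- nn_linear_fwd(par$fc2, h)
  gate <- nn_sigmoid(gpre)
  grep <- gate[, rep(seq_len(B), each = S), drop = FALSE]
  list(y = x * grep,
       cache = list(x = x, z = z, hm = hm, h = h, gate = gate, grep = grep,
                    B = B, S = S))
}

se_bwd <- function(par, cache, dy) {
  B <- cache$B; S <- cache$S
  x <- cache$x
  dx <- dy * cache$grep
  dgate <- matrix(0, nrow(cache$gate), B)
  for (b in seq_len(B)) {
    cols <- ((b - 1L) * S + 1L):(b * S)
    dgate[, b] <- rowSums(dy[, cols, drop = FALSE] * x[, cols, drop = FALSE])
  }
  dgpre <- dgate * cache$gate * (1 - cache$gate)
  g2 <- nn_linear_bwd(par$fc2, cache$h, dgpre)
  dh <- g2$dx * cache$hm
  g1 <- nn_linear_bwd(par$fc1, cache$z, dh)
  dz <- g1$dx
  dx <- dx + dz[, rep(seq_len(B), each = S), drop = FALSE] / S
  list(dx = dx,
       grads = list(fc1 = list(W = g1$dW, b = g1$db),
                    fc2 = list(W = g2$dW, b = g2$db)))
}

# Channel-wise max over contiguous neighbor blocks. x is [C x (M*K)] with
# the K neighbor columns of each of the M groups contiguous; returns the
# per-channel max [C x M] plus the argmax needed for the backward scatter.
maxpool_fwd <- function(x, K) {
  r <- maxpool_fwd_cpp(x, as.integer(K))
  list(y = r$y, argm = r$argm, K = as.integer(K), M = ncol(x) %/% K)
}

maxpool_bwd <- function(cache, dy) {
  C <- nrow(dy); M <- cache$M; K <- cache$K
  dx <- matrix(0, C, M * K)
  cols <- (rep(seq_len(M) - 1L, each = C)) * K + as.vector(cache$argm)
  li <- (cols - 1L) * C + rep(seq_len(C), M)
  dx[li] <- as.vector(dy)
  dx
}

# Geometric affine normalisation of grouped neighbor features. For each
# group (one center with its K neighbors) the residuals r = neighbor - center
# are scaled by the group's standard deviation (over all channels and
# neighbors, unbiased, epsilon-stabilised), then transformed by learnable
# per-channel alpha/beta.
affine_fwd <- function(par, gn, fc_rep, K, eps = 1e-5) {
  C <- nrow(gn)
  M <- ncol(gn) %/% K # number of groups
  r <- gn - fc_rep
  rg <- matrix(r, nrow = C * K) # columns = groups
  n <- C * K
  mu <- .colMeans(rg, n, M)
  ss <- .colSums(rg * rg, n, M) - n * mu * mu
  ss[ss < 0] <- 0
  s <- sqrt(ss / max(1, n - 1))
  denom <- matrix(rep(s + eps, each = C * K), nrow = C * K)
  rn <- matrix(rg / denom, nrow = C)
  y <- par$a * rn + par$b
  list(y = y,
       cache = list(r = r, rn = rn, s = s, mu = mu, n = n, K = K, M = M, eps = eps))
}

affine_bwd <- function(par, cache, dy) {
  C <- nrow(dy)
  K <- cache$K; M <- cache$M; n <- cache$n
  da <- rowSums(dy * cache$rn)
  db <- rowSums(dy)
  drn <- dy * par$a
  denom_g <- cache$s + cache$eps
  # direct path
  drg <- matrix(drn, nrow = C * K) / matrix(rep(denom_g, each = C * K), nrow = C * K)
  # path through the group standard deviation
  rg <- matrix(cache$r, nrow = C * K)
  dLds <- -colSums(matrix(drn, nrow = C * K) * rg) / denom_g^2
  s_safe <- pmax(cache$s, 1e-12)
  dsdr_scale <- dLds / (max(1, n - 1) * s_safe)
  drg <- drg + sweep(sweep(rg, 2L, cache$mu), 2L, dsdr_scale, "*")
  dr <- matrix(drg, nrow = C)
  # r = gn - fc_rep
  dfc_rep <- -dr
  list(dgn = dr, dfc_rep = dfc_rep, grads = list(a = da, b = db))
}

# Scatter-add columns of dG into columns of a [C x N] zero matrix at `idx`.
scatter_add_cols <- function(C, N, dG, idx) {
  scatter_add_cols_cpp(dG, as.integer(idx), as.integer(N))
}
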