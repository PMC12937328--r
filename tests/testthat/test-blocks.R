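test_that("partial convolution transforms 1/4 of the channels and copies the rest bit-exactly", {
  C <- 64L; L <- 20L
  x <- withr::with_seed(1, matrix(rnorm(C * L), C, L))
  w <- pconv_weights(C, seed = 2)
  y <- pconv1d(x, pconv_config(), w)
  expect_equal(dim(y), dim(x))
  expect_identical(y[17:64, ], x[17:64, ]) # untouched block, bit-exact
  expect_false(isTRUE(all.equal(y[1:16, ], x[1:16, ])))
  expect_equal(y[1:16, ], w$W %*% x[1:16, ] + w$b)
})

test_that("partial ratio 1 reduces to a full pointwise convolution", {
  C <- 12L; L <- 9L
  x <- withr::with_seed(3, matrix(rnorm(C * L), C, L))
  cfg1 <- pconv_config(partial_ratio = 1)
  w <- pconv_weights(C, cfg1, seed = 4)
  expect_equal(pconv1d(x, cfg1, w), w$W %*% x + w$b)
})

test_that("batched [B, C, L] inputs are handled consistently", {
  C <- 8L; L <- 6L; B <- 3L
  xb <- withr::with_seed(5, array(rnorm(B * C * L), c(B, C, L)))
  w <- pconv_weights(C, seed = 6)
  yb <- pconv1d(xb, pconv_config(), w)
  expect_equal(dim(yb), dim(xb))
  for (b in seq_len(B)) {
    xm <- matrix(xb[b, , ], C, L)
    expect_equal(matrix(yb[b, , ], C, L), pconv1d(xm, pconv_config(), w))
  }
})

test_that("zeroed convolutions reduce the block to its skip-plus-passthrough form", {
  C <- 8L; L <- 10L
  x <- withr::with_seed(7, matrix(rnorm(C * L), C, L))
  # full-width convolution (ratio 1): zero weights kill the entire residual
  # path, so the block is exactly ReLU
  cfg1 <- pconv_config(partial_ratio = 1)
  w1 <- pconv_resblock_weights(C, cfg1, seed = 8)
  w1$par$c1$W[] <- 0; w1$par$c1$b[] <- 0
  w1$par$c2$W[] <- 0; w1$par$c2$b[] <- 0
  y1 <- pconv_resblock(x, cfg1, w1, train = FALSE)
  expect_equal(y1, pmax(x, 0), tolerance = 1e-5)

  # partial block: the convolved slice is zeroed, but the untouched 3/4
  # still pass through the residual branch by construction, doubling the
  # skip contribution there
  w <- pconv_resblock_weights(C, seed = 8)
  w$par$c1$W[] <- 0; w$par$c1$b[] <- 0
  w$par$c2$W[] <- 0; w$par$c2$b[] <- 0
  y <- pconv_resblock(x, pconv_config(), w, train = FALSE)
  cp <- 2L # ceiling(8 / 4)
  expect_equal(y[seq_len(cp), ], pmax(x[seq_len(cp), ], 0), tolerance = 1e-5)
  expect_equal(y[-seq_len(cp), ], pmax(2 * x[-seq_len(cp), ], 0),
               tolerance = 1e-5)
})

test_that("the residual block never mixes the untouched channels through a convolution", {
  # with the second BN forced to identity-ish eval stats, the untouched
  # channels of the residual branch equal BN(pconv(x)) restricted to the
  # pass-through slice, i.e. depend only on their own values
  C <- 16L; L <- 12L
  x <- withr::with_seed(9, matrix(rnorm(C * L), C, L))
  w <- pconv_resblock_weights(C, seed = 10)
  x2 <- x
  x2[1:4, ] <- x2[1:4, ] + 5 # perturb only the convolved slice
  y <- pconv_resblock(x, pconv_config(), w, train = FALSE)
  y2 <- pconv_resblock(x2, pconv_config(), w, train = FALSE)
  # untouched channels of the first conv pass straight through conv1;
  # conv2 also leaves them alone, so rows 5..16 of the residual branch
  # cannot react to the perturbation of rows 1..4
  d1 <- (y2 - y)[5:16, ]
  # the only coupling for rows 5..16 is the residual add of x itself,
  # which was not perturbed there
  expect_lt(max(abs(d1)), 1e-8)
})

test_that("gradients flow through the residual skip even with zeroed convolutions", {
  C <- 3L; L <- 4L
  x <- withr::with_seed(11, matrix(rnorm(C * L), C, L))
  w <- pconv_resblock_weights(C, seed = 12)
  w$par$c1$W[] <- 0; w$par$c2$W[] <- 0
  w$par$c1$b[] <- 0; w$par$c2$b[] <- 0
  fw <- pointid:::resblock_fwd(w$par, w$buf, x, train = TRUE, partial = TRUE)
  dy <- matrix(1, C, L)
  bw <- pointid:::resblock_bwd(w$par, fw$cache, dy, train = TRUE, partial = TRUE)
  # finite-difference check of dL/dx for L = sum(y)
  eps <- 1e-6
  fd <- matrix(0, C, L)
  for (i in seq_len(C * L)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fp <- pointid:::resblock_fwd(w$par, w$buf, xp, train = TRUE, partial = TRUE)
    fm <- pointid:::resblock_fwd(w$par, w$buf, xm, train = TRUE, partial = TRUE)
    fd[i] <- (sum(fp$y) - sum(fm$y)) / (2 * eps)
  }
  expect_equal(bw$dx, fd, tolerance = 1e-4)
  expect_true(any(abs(bw$dx) > 0))
})

test_that("SE gates lie strictly in (0,1) and gate the input multiplicatively", {
  C <- 16L; L <- 10L
  w <- se_weights(C, se_config(8), seed = 13)
  # all-zero input stays zero
  expect_equal(se_block(matrix(0, C, L), se_config(8), w), matrix(0, C, L))
  # zero weights: gate = sigmoid(0) = 0.5 exactly
  w0 <- w
  w0$fc1$W[] <- 0; w0$fc1$b[] <- 0; w0$fc2$W[] <- 0; w0$fc2$b[] <- 0
  x <- withr::with_seed(14, matrix(rnorm(C * L), C, L))
  expect_equal(se_block(x, se_config(8), w0), 0.5 * x)
  # |output| <= |input| elementwise for arbitrary weights
  withr::with_seed(15, {
    for (r in 1:20) {
      wr <- se_weights(C, se_config(8))
      xr <- matrix(rnorm(C * L), C, L)
      yr <- se_block(xr, se_config(8), wr)
      expect_true(all(abs(yr) <= abs(xr) + 1e-12))
      gates <- yr / xr
      gates <- gates[is.finite(gates)]
      expect_true(all(gates > 0 & gates < 1))
    }
  })
})

test_that("SE clamps the bottleneck width for very narrow inputs", {
  expect_warning(w <- se_weights(4, se_config(8)), "clamped")
  expect_equal(nrow(w$fc1$W), 1L)
})

test_that("geometric affine normalizes group scale and survives degenerate groups", {
  B <- 1L; S <- 4L; K <- 6L; C <- 5L
  withr::with_seed(16, {
    f <- array(rnorm(B * S * K * C), c(B, S, K, C))
  })
  gn <- grouped_neighborhood(f)
  a <- rep(1, C); b0 <- rep(0, C)
  out <- geometric_affine(gn, a, b0)
  expect_equal(dim(out$features), dim(f))
  # scaling every input by 10 leaves the normalized output invariant
  # (centers default to the first neighbor slot, which scales too)
  gn10 <- grouped_neighborhood(f * 10)
  out10 <- geometric_affine(gn10, a, b0)
  expect_equal(out10$features, out$features, tolerance = 1e-3)
  # constant group: finite output, no NaN
  gconst <- grouped_neighborhood(array(2, c(1, 1, K, C)))
  oc <- geometric_affine(gconst, a, b0)
  expect_true(all(is.finite(oc$features)))
  expect_equal(max(abs(oc$features)), 0) # residuals are zero
})

test_that("geometric affine with unit alpha on a unit-variance group is near identity on residuals", {
  K <- 8L; C <- 4L
  withr::with_seed(17, {
    r <- array(rnorm(1 * 1 * K * C), c(1, 1, K, C))
  })
  r <- r - mean(r)
  r <- r / sd(r)
  centf <- array(0, c(1, 1, C))
  gn <- grouped_neighborhood(r)
  out <- geometric_affine(gn, rep(1, C), rep(0, C), center_features = centf)
  expect_equal(out$features, r, tolerance = 1e-4)
})
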