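test_that("model configuration validates its invariants", {
  expect_error(model_config(stage_points = c(64, 64), stage_channels = c(8, 16)),
               "strictly decreasing")
  expect_error(model_config(input_points = 32, stage_points = c(64, 16),
                            stage_channels = c(8, 16)), "must not exceed")
  expect_error(model_config(stage_points = c(64, 32), stage_channels = c(8, 16, 32)),
               "equal length")
  expect_error(model_config(dropout = 1), "dropout")
  # defaults: halving centers, doubling channels
  cfg <- model_config(input_points = 1024)
  expect_equal(cfg$stage_points, c(512L, 256L, 128L, 64L))
  expect_equal(cfg$stage_channels, c(128L, 256L, 512L, 1024L))
})

test_that("forward produces one logit row per cloud and rejects wrong point counts", {
  m <- build_model(tiny_model_config(), seed = 1)
  X <- tiny_batch(B = 2)
  lg <- forward(m, X)
  expect_equal(dim(lg), c(2L, 4L))
  expect_true(all(is.finite(lg)))
  expect_error(forward(m, X[, 1:16, , drop = FALSE]), "resample first")
})

test_that("evaluation passes are deterministic and batch-independent", {
  m <- build_model(tiny_model_config(variant = "full"), seed = 2)
  X <- tiny_batch(B = 2)
  expect_identical(forward(m, X), forward(m, X))
  # duplicated cloud in one batch: identical rows
  Xd <- X
  Xd[2, , ] <- X[1, , ]
  lg <- forward(m, Xd)
  expect_equal(lg[1, ], lg[2, ])
  # single-cloud pass equals its row in the batched pass
  lg1 <- forward(m, X[1, , ])
  expect_equal(lg1[1, ], forward(m, X)[1, ])
})

test_that("eval logits are invariant to input point permutation", {
  m <- build_model(tiny_model_config(variant = "full"), seed = 3)
  cl <- tiny_batch(B = 1)[1, , ]
  base <- forward(m, cl)
  withr::with_seed(4, {
    for (r in 1:3) {
      perm <- sample(nrow(cl))
      expect_lt(max(abs(forward(m, cl[perm, ]) - base)), 1e-4)
    }
  })
})

test_that("the three variants differ only in their structural flags", {
  cfgb <- tiny_model_config(variant = "baseline")
  cfgd <- tiny_model_config(variant = "dlf_only")
  cfgf <- tiny_model_config(variant = "full")
  mb <- build_model(cfgb, seed = 5)
  md <- build_model(cfgd, seed = 5)
  mf <- build_model(cfgf, seed = 5)
  # baseline and dlf_only share every parameter shape (grouping width is
  # not a parameter); full differs in conv shapes and adds SE
  shapes <- function(m) rapply(m$par, function(x) {
    d <- dim(x); if (is.null(d)) d <- length(x)
    paste(d, collapse = "x")
  }, how = "unlist")
  expect_identical(shapes(mb), shapes(md))
  expect_true(any(grepl("se", names(shapes(mf)))))
  expect_false(any(grepl("se", names(shapes(mb)))))
  # config diff is exactly the variant flag
  expect_identical(cfgb[setdiff(names(cfgb), "variant")],
                   cfgf[setdiff(names(cfgf), "variant")])
})

test_that("full variant with ratio 1 and saturated SE gates reproduces dlf_only", {
  cfgd <- tiny_model_config(variant = "dlf_only")
  cfgf <- tiny_model_config(variant = "full", partial_ratio = 1)
  md <- build_model(cfgd, seed = 6)
  mf <- build_model(cfgf, seed = 7)
  # share all common weights; saturate the SE gates (sigmoid -> 1)
  mf$par$embed <- md$par$embed
  for (i in seq_along(cfgd$stage_points)) {
    mf$par$stages[[i]]$affine <- md$par$stages[[i]]$affine
    mf$par$stages[[i]]$transfer <- md$par$stages[[i]]$transfer
    for (j in seq_along(md$par$stages[[i]]$pre)) {
      src <- md$par$stages[[i]]$pre[[j]]
      src$c1$cp <- nrow(src$c1$W); src$c2$cp <- nrow(src$c2$W)
      mf$par$stages[[i]]$pre[[j]] <- src
    }
    for (j in seq_along(md$par$stages[[i]]$pos)) {
      src <- md$par$stages[[i]]$pos[[j]]
      src$c1$cp <- nrow(src$c1$W); src$c2$cp <- nrow(src$c2$W)
      mf$par$stages[[i]]$pos[[j]] <- src
    }
    mf$par$stages[[i]]$se$fc1$W[] <- 0
    mf$par$stages[[i]]$se$fc1$b[] <- 0
    mf$par$stages[[i]]$se$fc2$W[] <- 0
    mf$par$stages[[i]]$se$fc2$b[] <- 40 # sigmoid(40) = 1 to double precision
  }
  mf$par$cls <- md$par$cls
  X <- tiny_batch(B = 2)
  expect_equal(forward(mf, X), forward(md, X), tolerance = 1e-8)
})

test_that("parameter counting is exact and independent of input size", {
  # a fully connected 512 -> 256 layer with bias
  expect_equal(length(pointid:::nn_linear_init(512, 256)$W) + 256, 131328)
  # classifier head FC(512,256) + FC(256,10) with biases
  expect_equal(131328 + 256 * 10 + 10, 133898)
  m1 <- build_model(tiny_model_config(), seed = 8)
  cfg2 <- tiny_model_config()
  cfg2$input_points <- 64L
  cfg2$stage_points <- c(32L, 8L)
  m2 <- build_model(cfg2, seed = 9)
  expect_identical(count_parameters(m1), count_parameters(m2))
})

test_that("analytic FLOPs follow the MAC convention and the partial-conv ratio law", {
  # a single fully connected layer contributes 2 * Cin * Cout
  cfg0 <- tiny_model_config()
  m <- build_model(cfg0, seed = 10)
  # partial-conv blocks cost 1/16 of full blocks: compare identical
  # architectures differing only in partial ratio, after removing the
  # block-free backbone cost
  base <- tiny_model_config(variant = "full")
  nb <- base; nb$pre_blocks <- 0L; nb$pos_blocks <- 0L
  full_ratio <- base; full_ratio$partial_ratio <- 1
  f_blocks_partial <- count_flops(build_model(base, seed = 1)) -
    count_flops(build_model(nb, seed = 1))
  f_blocks_full <- count_flops(build_model(full_ratio, seed = 1)) -
    count_flops(build_model(nb, seed = 1))
  expect_equal(f_blocks_partial / f_blocks_full, 1 / 16, tolerance = 1e-10)
  # block FLOPs scale linearly with the center counts
  dbl <- base
  dbl$input_points <- 2L * base$input_points
  dbl$stage_points <- 2L * base$stage_points
  nbd <- dbl; nbd$pre_blocks <- 0L; nbd$pos_blocks <- 0L
  f2 <- count_flops(build_model(dbl, seed = 1)) -
    count_flops(build_model(nbd, seed = 1))
  expect_equal(f2 / f_blocks_partial, 2, tolerance = 1e-10)
})

test_that("complexity orderings across variants match the structural expectations", {
  pb <- profile_model(model_config(variant = "baseline"), resolutions = 1024)
  pd <- profile_model(model_config(variant = "dlf_only"), resolutions = 1024)
  pf <- profile_model(model_config(variant = "full"), resolutions = 1024)
  # dual-branch grouping doubles the grouped work
  expect_gt(pd$flops_1024, pb$flops_1024)
  # partial convolutions cut both parameters and FLOPs
  expect_lt(pf$params, pd$params)
  expect_lt(pf$params, pb$params)
  expect_lt(pf$flops_1024, pd$flops_1024)
  # grouping width is free in parameters
  expect_equal(pb$params, pd$params)
})

test_that("one training step sends gradient to every trainable tensor", {
  cfg <- tiny_model_config(variant = "full")
  m <- build_model(cfg, seed = 11)
  X <- tiny_batch(B = 4, seed = 12)
  withr::with_seed(13, {
    fw <- pointid:::dk_forward(m, X, train = TRUE, keep_cache = TRUE)
    ls <- pointid:::ce_loss_smoothed(fw$logits, c(1L, 2L, 3L, 4L), 0.1)
    g <- pointid:::dk_backward(m, fw, ls$dlogits)
  })
  leaves <- pointid:::flat_params(g)
  expect_true(length(leaves) > 20)
  nonzero <- vapply(leaves, function(x) any(abs(x) > 0), logical(1))
  expect_true(all(nonzero))
})

test_that("a saved model reloads to the identical function", {
  m <- build_model(tiny_model_config(variant = "full"), seed = 14)
  tmp <- tempfile(fileext = ".rds")
  save_model(m, tmp)
  expect_true(file.exists(paste0(tmp, ".yaml")))
  m2 <- load_model(tmp)
  X <- tiny_batch(B = 2, seed = 15)
  expect_identical(forward(m, X), forward(m2, X))
  expect_identical(count_parameters(m), count_parameters(m2))
})
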