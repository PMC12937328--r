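test_that("standard branch is exact KNN with self-inclusion", {
  cloud <- random_cloud(40, seed = 1)
  centers <- c(3L, 17L, 25L)
  cfg <- neighborhood_config(k = 1)
  expect_equal(as.vector(standard_branch(cloud, centers, cfg)), centers)
  cfg5 <- neighborhood_config(k = 5)
  expect_identical(standard_branch(cloud, centers, cfg5),
                   matrix(oracle_knn(cloud[centers, , drop = FALSE], cloud, 5),
                          3, 5))
  cfgN <- neighborhood_config(k = 40)
  expect_setequal(standard_branch(cloud, centers[1], cfgN)[1, ], 1:40)
})

test_that("dilated branch draws from the 2k candidate shell", {
  cloud <- random_cloud(50, seed = 2)
  centers <- 1:10
  cfg <- neighborhood_config(k = 6, jitter_delta = 0, rng_seed = 9)
  shell <- knn_indices(cloud[centers, , drop = FALSE], cloud, 12)
  withr::with_seed(3, {
    got <- dilated_branch(cloud, centers, cfg, mode = "train")
    for (i in seq_along(centers))
      expect_true(all(got[i, ] %in% shell[i, ]))
  })
  # N = 2k boundary: the shell is the whole cloud
  small <- cloud[1:12, ]
  withr::with_seed(4, {
    got <- dilated_branch(small, 1:3, cfg, mode = "train")
    expect_true(all(got %in% 1:12))
    expect_equal(ncol(got), 6)
    # without replacement: no duplicates per center
    expect_true(all(apply(got, 1, function(r) !anyDuplicated(r))))
  })
})

test_that("dilated branch falls back gracefully when 2k exceeds the cloud", {
  cloud <- random_cloud(8, seed = 5)
  cfg <- neighborhood_config(k = 6, jitter_delta = 0)
  withr::with_seed(6, {
    expect_warning(got <- dilated_branch(cloud, 1:2, cfg, mode = "train"),
                   "falls back")
    expect_true(all(got %in% 1:8))
  })
})

test_that("dilated subsampling is uniform over the candidate shell", {
  cloud <- random_cloud(30, seed = 7)
  cfg <- neighborhood_config(k = 4, jitter_delta = 0)
  shell <- knn_indices(cloud[1, , drop = FALSE], cloud, 8)[1, ]
  counts <- setNames(numeric(8), shell)
  withr::with_seed(8, {
    for (r in 1:10000) {
      got <- pointid:::dilated_indices(cloud, cloud[1, , drop = FALSE], 4)
      counts[as.character(got)] <- counts[as.character(got)] + 1
    }
  })
  freq <- counts / 10000
  expect_true(all(abs(freq - 0.5) <= 0.02))
})

test_that("evaluation-mode dilated sampling is reproducible and leaves the RNG alone", {
  cloud <- random_cloud(40, seed = 9)
  cfg <- neighborhood_config(k = 5, rng_seed = 123)
  a <- dilated_branch(cloud, 1:4, cfg, mode = "eval")
  state <- runif(1) # arbitrary RNG consumption in between
  b <- dilated_branch(cloud, 1:4, cfg, mode = "eval")
  expect_identical(a, b)
})

test_that("forcing the dilated sampler onto the first k candidates recovers the standard branch", {
  # degenerate-equivalence oracle: with no jitter the first k of the
  # 2k-candidate shell are exactly the standard KNN
  cloud <- random_cloud(60, seed = 10)
  centers <- c(2L, 30L, 59L)
  cfg <- neighborhood_config(k = 7)
  shell <- knn_indices(cloud[centers, , drop = FALSE], cloud, 14)
  expect_identical(shell[, 1:7], standard_branch(cloud, centers, cfg))
})

test_that("fusion concatenates branches along the neighbor dimension", {
  # index-level fusion conserves the multiset of both branches
  cloud <- random_cloud(50, seed = 11)
  cfg <- neighborhood_config(k = 6, jitter_delta = 0)
  std <- standard_branch(cloud, 1:5, cfg)
  dil <- withr::with_seed(12, dilated_branch(cloud, 1:5, cfg, mode = "train"))
  fused <- fuse_branches(std, dil)
  expect_equal(dim(fused), c(5L, 12L))
  expect_identical(fused[, 1:6], std)
  expect_identical(fused[, 7:12], dil)
  for (i in 1:5)
    expect_equal(sort(fused[i, ]), sort(c(std[i, ], dil[i, ])))
  expect_error(fuse_branches(std, dil[, 1:3]), "share their shape")
})

test_that("feature-level fusion yields a 2K neighborhood and recovers the branches", {
  B <- 2L; S <- 64L; K <- 24L; C <- 16L
  mk <- function(seed) {
    withr::with_seed(seed, grouped_neighborhood(
      array(rnorm(B * S * K * C), c(B, S, K, C)),
      array(rnorm(B * S * K * 3), c(B, S, K, 3)),
      array(rnorm(B * S * 3), c(B, S, 3))))
  }
  std <- mk(1); dil <- mk(2)
  fused <- fuse_branches(std, dil)
  expect_equal(dim(fused$features), c(B, S, 2L * K, C))
  expect_equal(fused$features[, , 1:K, ], std$features)
  expect_equal(fused$features[, , (K + 1):(2 * K), ], dil$features)
  # duplicating one branch duplicates the two halves
  dup <- fuse_branches(std, std)
  expect_equal(dup$features[, , 1:K, ], dup$features[, , (K + 1):(2 * K), ])
  bad <- mk(3); bad$features <- bad$features[, , , 1:8, drop = FALSE]
  expect_error(fuse_branches(std, bad), "shapes differ")
})

test_that("edge-feature aggregation is neighbor-permutation invariant and matches the loop oracle", {
  B <- 1L; S <- 3L; K <- 4L; C <- 5L; D <- 7L
  withr::with_seed(13, {
    gn <- grouped_neighborhood(array(rnorm(B * S * K * C), c(B, S, K, C)),
                               array(rnorm(B * S * K * 3), c(B, S, K, 3)),
                               array(rnorm(B * S * 3), c(B, S, 3)))
    centf <- array(rnorm(B * S * C), c(B, S, C))
    mlp <- list(W = matrix(rnorm(D * (2 * C + 3)), D), b = rnorm(D))
  })
  out <- aggregate_edge_features(gn, centf, mlp)
  expect_equal(dim(out), c(B, S, D))

  # explicit per-edge maximum oracle
  for (s in 1:S) {
    edges <- sapply(1:K, function(t) {
      e <- c(centf[1, s, ], gn$features[1, s, t, ],
             gn$neighbor_xyz[1, s, t, ] - gn$center_xyz[1, s, ])
      pmax(mlp$W %*% e + mlp$b, 0)
    })
    expect_equal(out[1, s, ], apply(edges, 1, max))
  }

  # shuffling neighbor slots changes nothing
  perm <- c(3, 1, 4, 2)
  gn2 <- gn
  gn2$features <- gn$features[, , perm, , drop = FALSE]
  gn2$neighbor_xyz <- gn$neighbor_xyz[, , perm, , drop = FALSE]
  expect_equal(aggregate_edge_features(gn2, centf, mlp), out)

  # all-identical neighbors collapse to the single transformed edge
  gn3 <- gn
  for (t in 1:K) {
    gn3$features[, , t, ] <- gn$features[, , 1, ]
    gn3$neighbor_xyz[, , t, ] <- gn$neighbor_xyz[, , 1, ]
  }
  one <- aggregate_edge_features(gn3, centf, mlp)
  e1 <- c(centf[1, 1, ], gn3$features[1, 1, 1, ],
          gn3$neighbor_xyz[1, 1, 1, ] - gn3$center_xyz[1, 1, ])
  expect_equal(one[1, 1, ], pmax(as.vector(mlp$W %*% e1 + mlp$b), 0))

  # channel mismatch with the shared MLP is rejected
  badmlp <- list(W = matrix(0, D, 2 * C + 2), b = rnorm(D))
  expect_error(aggregate_edge_features(gn, centf, badmlp), "input channels")
})
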