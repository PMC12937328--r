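# Dual-scale neighborhood grouping: a standard k-nearest-neighbor branch and
# a stochastically dilated branch that draws k neighbors uniformly from the
# 2k-nearest candidate shell, fused along the neighbor dimension into a
# 2k-neighbor grouped representation.

#' Neighborhood grouping configuration
#'
#' @param k neighbors per branch (default 24, the optimum of the neighborhood
#'   size sweep; 20 is the other commonly used value).
#' @param candidate_multiplier size of the dilated candidate shell as a
#'   multiple of `k`; fixed at 2 (the "2K shell").
#' @param jitter_delta half-width of the uniform per-axis query jitter applied
#'   by the dilated branch in training mode, in normalized coordinate units.
#' @param rng_seed seed for the dedicated generator used by evaluation-mode
#'   stochastic sampling, making evaluation reproducible.
#' @return a list of class `neighborhood_config`.
#' @export
neighborhood_config <- function(k = 24, candidate_multiplier = 2,
                                jitter_delta = 0.2, rng_seed = 42) {
  k <- as.integer(k)
  if (k < 1L) stopf("`k` must be >= 1")
  if (as.integer(candidate_multiplier) != 2L)
    stopf("`candidate_multiplier` is fixed at 2 (the 2K candidate shell)")
  if (jitter_delta < 0 || jitter_delta >= 1)
    stopf("`jitter_delta` must lie in [0, 1)")
  structure(list(k = k, candidate_multiplier = 2L,
                 jitter_delta = jitter_delta,
                 rng_seed = as.integer(rng_seed)),
            class = "neighborhood_config")
}

#' Standard k-nearest-neighbor branch
#'
#' Exact k nearest neighbors of each center point; the center itself is
#' eligible (zero distance) and appears first.
#'
#' @param cloud N x 3 reference cloud.
#' @param centers integer vector of center indices into `cloud`.
#' @param cfg a [neighborhood_config()].
#' @return integer matrix `length(centers)` x k of neighbor indices,
#'   ascending by distance.
#' @export
standard_branch <- function(cloud, centers, cfg) {
  validate_cloud(cloud)
  knn_indices(cloud[centers, , drop = FALSE], cloud, cfg$k)
}

# Core of the dilated branch; assumes the caller controls the RNG state.
dilated_indices <- function(cloud, queries, k) {
  n <- nrow(cloud)
  kc <- 2L * k
  if (kc > n) {
    warnf("2k (%d) exceeds the cloud size (%d); candidate shell falls back to all points",
          kc, n)
    cand <- knn_indices(queries, cloud, n) # distance-ordered fallback shell
  } else {
    cand <- knn_indices(queries, cloud, kc)
  }
  nc <- ncol(cand)
  out <- matrix(0L, nrow(cand), k)
  replace <- nc < k
  for (i in seq_len(nrow(cand))) {
    pick <- sample.int(nc, k, replace = replace)
    out[i, ] <- cand[i, pick]
  }
  out
}

#' Stochastically dilated k-nearest-neighbor branch
#'
#' Selects the 2k nearest candidate neighbors of each (optionally jittered)
#' center and draws k of them uniformly without replacement, enlarging the
#' effective receptive field. In `"train"` mode the query coordinate of each
#' center is first shifted by a uniform per-axis offset in
#' `[-jitter_delta, jitter_delta]` and draws come from the current RNG
#' stream; in `"eval"` mode no jitter is applied and a dedicated generator
#' seeded from `cfg$rng_seed` makes the output reproducible. Reference
#' points are never moved.
#'
#' @inheritParams standard_branch
#' @param mode `"train"` or `"eval"`.
#' @return integer matrix `length(centers)` x k; every index lies in the
#'   2k-candidate shell of its center.
#' @export
dilated_branch <- function(cloud, centers, cfg, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  validate_cloud(cloud)
  q <- cloud[centers, , drop = FALSE]
  if (mode == "eval") {
    return(with_seed_preserved(cfg$rng_seed, dilated_indices(cloud, q, cfg$k)))
  }
  if (cfg$jitter_delta > 0) {
    q <- q + matrix(stats::runif(length(q), -cfg$jitter_delta, cfg$jitter_delta),
                    nrow(q), 3L)
  }
  dilated_indices(cloud, q, cfg$k)
}

#' Grouped neighborhood container
#'
#' Per-center fused neighbor features: `features` is
#' `[batch, centers, neighbors, channels]`, `neighbor_xyz` is
#' `[batch, centers, neighbors, 3]` and `center_xyz` is `[batch, centers, 3]`.
#'
#' @param features 4-d numeric array.
#' @param neighbor_xyz 4-d numeric array, last dimension 3.
#' @param center_xyz 3-d numeric array, last dimension 3.
#' @return a list of class `grouped_neighborhood`.
#' @export
grouped_neighborhood <- function(features, neighbor_xyz = NULL, center_xyz = NULL) {
  d <- dim(features)
  if (length(d) != 4L) stopf("`features` must be a 4-d array [B, S, K, C]")
  if (!is.null(neighbor_xyz)) {
    dn <- dim(neighbor_xyz)
    if (length(dn) != 4L || any(dn[1:3] != d[1:3]) || dn[4L] != 3L)
      stopf("`neighbor_xyz` must be [B, S, K, 3] matching `features`")
  }
  if (!is.null(center_xyz)) {
    dc <- dim(center_xyz)
    if (length(dc) != 3L || any(dc[1:2] != d[1:2]) || dc[3L] != 3L)
      stopf("`center_xyz` must be [B, S, 3] matching `features`")
  }
  structure(list(features = features, neighbor_xyz = neighbor_xyz,
                 center_xyz = center_xyz),
            class = "grouped_neighborhood")
}

#' Fuse the two neighborhood branches along the neighbor dimension
#'
#' Concatenates the standard-branch and dilated-branch groupings so that the
#' fused neighborhood holds exactly 2k members: the first k slots come from
#' the standard branch, the last k from the dilated branch, each in
#' branch-internal order. Duplicated neighbors (a point selected by both
#' branches) are kept; the downstream max-pooling makes them harmless.
#'
#' Accepts either two index matrices (as returned by [standard_branch()] and
#' [dilated_branch()]) or two [grouped_neighborhood()] objects.
#'
#' @param std,dil the two branches, of identical shape.
#' @return the fused object of the same type with 2k neighbors.
#' @export
fuse_branches <- function(std, dil) {
  if (is.matrix(std) && is.matrix(dil)) {
    if (!all(dim(std) == dim(dil)))
      stopf("branch index matrices must share their shape")
    return(cbind(std, dil))
  }
  if (inherits(std, "grouped_neighborhood") && inherits(dil, "grouped_neighborhood")) {
    ds <- dim(std$features); dd <- dim(dil$features)
    if (any(ds != dd))
      stopf("branch feature shapes differ: [%s] vs [%s]",
            paste(ds, collapse = ","), paste(dd, collapse = ","))
    cat4 <- function(a, b) {
      if (is.null(a) || is.null(b)) return(NULL)
      da <- dim(a)
      out <- array(0, c(da[1L], da[2L], 2L * da[3L], da[4L]))
      out[, , seq_len(da[3L]), ] <- a
      out[, , da[3L] + seq_len(da[3L]), ] <- b
      out
    }
    cx <- std$center_xyz
    return(grouped_neighborhood(cat4(std$features, dil$features),
                                cat4(std$neighbor_xyz, dil$neighbor_xyz),
                                cx))
  }
  stopf("`std` and `dil` must both be index matrices or both grouped neighborhoods")
}

#' Edge-feature aggregation over a grouped neighborhood
#'
#' For every neighbor the edge feature is the channel-wise concatenation of
#' the center feature, the neighbor feature and the relative position
#' (neighbor xyz - center xyz). A shared one-layer perceptron (weights `W`
#' `[D x (2C+3)]`, bias `b`, ReLU) transforms each edge, and channel-wise
#' max-pooling across the neighbor dimension yields a permutation-invariant
#' local descriptor.
#'
#' @param grouped a [grouped_neighborhood()] carrying `neighbor_xyz` and
#'   `center_xyz`.
#' @param center_features `[B, S, C]` array of center-point features.
#' @param shared_mlp list with elements `W` and `b`.
#' @return `[B, S, D]` array of aggregated local features.
#' @export
aggregate_edge_features <- function(grouped, center_features, shared_mlp) {
  stopifnot(inherits(grouped, "grouped_neighborhood"))
  if (is.null(grouped$neighbor_xyz) || is.null(grouped$center_xyz))
    stopf("`grouped` must carry neighbor and center coordinates")
  d <- dim(grouped$features) # B, S, K, C
  B <- d[1L]; S <- d[2L]; K <- d[3L]; C <- d[4L]
  Din <- 2L * C + 3L
  if (ncol(shared_mlp$W) != Din)
    stopf("shared MLP expects %d input channels, edge features have %d",
          ncol(shared_mlp$W), Din)
  D <- nrow(shared_mlp$W)
  out <- array(0, c(B, S, D))
  for (b in seq_len(B)) {
    # [C x S*K] matrices, neighbor fastest
    gn <- matrix(aperm(grouped$features[b, , , , drop = FALSE], c(4L, 3L, 2L, 1L)),
                 nrow = C)
    nx <- matrix(aperm(grouped$neighbor_xyz[b, , , , drop = FALSE], c(4L, 3L, 2L, 1L)),
                 nrow = 3L)
    cfeat <- matrix(aperm(center_features[b, , , drop = FALSE], c(3L, 2L, 1L)),
                    nrow = C)
    cx <- matrix(aperm(grouped$center_xyz[b, , , drop = FALSE], c(3L, 2L, 1L)),
                 nrow = 3L)
    rep_idx <- rep(seq_len(S), each = K)
    edge <- rbind(cfeat[, rep_idx, drop = FALSE], gn,
                  nx - cx[, rep_idx, drop = FALSE])
    h <- shared_mlp$W %*% edge + shared_mlp$b
    h[h < 0] <- 0
    pooled <- maxpool_fwd(h, K)$y # [D x S]
    out[b, , ] <- t(pooled)
  }
  out
}
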