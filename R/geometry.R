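# Exact geometric primitives shared by the grouping modules and the network:
# brute-force pairwise distances, k-nearest neighbors, farthest point
# sampling and unit-sphere normalization. All contracts are exact (no
# approximate neighbor search) so they can be verified against independent
# oracles.

#' Validate a point cloud matrix
#'
#' A point cloud is an N x 3 numeric matrix of finite coordinates, N >= 1.
#' Used internally by every operation that consumes clouds; exported because
#' callers assembling clouds by hand find it convenient.
#'
#' @param cloud numeric matrix with 3 columns.
#' @param arg name used in error messages.
#' @return the validated cloud, invisibly.
#' @export
validate_cloud <- function(cloud, arg = "cloud") {
  if (!is.matrix(cloud) || !is.numeric(cloud))
    stopf("`%s` must be a numeric matrix with 3 columns", arg)
  if (ncol(cloud) != 3L)
    stopf("`%s` must have exactly 3 columns (x, y, z), got %d", arg, ncol(cloud))
  if (nrow(cloud) < 1L)
    stopf("`%s` must contain at least one point", arg)
  if (!all(is.finite(cloud)))
    stopf("`%s` contains non-finite coordinates", arg)
  invisible(cloud)
}

# Squared Euclidean distances, M x N. Distances are compared on squared
# values internally (monotone equivalent); true distances are only
# materialised where the caller asks for them.
pairwise_sqdist <- function(query, reference) {
  qq <- rowSums(query * query)
  rr <- rowSums(reference * reference)
  d2 <- outer(qq, rr, "+") - 2 * tcrossprod(query, reference)
  # the expanded form cancels catastrophically for near-coincident points;
  # recompute those few entries with the direct difference (exact zero for
  # identical points, e.g. a query matched against itself)
  tiny <- which(d2 < 1e-10)
  if (length(tiny)) {
    qi <- ((tiny - 1L) %% nrow(d2)) + 1L
    rj <- ((tiny - 1L) %/% nrow(d2)) + 1L
    diff <- query[qi, , drop = FALSE] - reference[rj, , drop = FALSE]
    d2[tiny] <- rowSums(diff * diff)
  }
  d2
}

#' Pairwise Euclidean distances between two point clouds
#'
#' @param query M x 3 matrix of query points.
#' @param reference N x 3 matrix of reference points.
#' @return M x N matrix of Euclidean distances; entry (i, j) is
#'   `||query[i,] - reference[j,]||`.
#' @examples
#' pairwise_distances(matrix(0, 1, 3), matrix(c(3, 4, 0), 1, 3)) # 5
#' @export
pairwise_distances <- function(query, reference) {
  validate_cloud(query, "query")
  validate_cloud(reference, "reference")
  sqrt(pairwise_sqdist(query, reference))
}

#' Exact k-nearest-neighbor indices
#'
#' For every query point, returns the indices of the `k` reference points at
#' smallest Euclidean distance, in ascending distance order. A query point
#' that is itself present in the reference (zero distance) is eligible and
#' returned first. Distance ties are broken by the smaller reference index,
#' which makes the result deterministic.
#'
#' @param query M x 3 matrix of query points.
#' @param reference N x 3 matrix of reference points.
#' @param k number of neighbors, `1 <= k <= nrow(reference)`.
#' @return integer matrix M x k; row i holds the neighbor indices of
#'   `query[i,]` into `reference`, nearest first.
#' @export
knn_indices <- function(query, reference, k) {
  validate_cloud(query, "query")
  validate_cloud(reference, "reference")
  k <- as.integer(k)
  if (k < 1L) stopf("`k` must be a positive integer")
  if (k > nrow(reference))
    stopf("`k` (%d) exceeds the reference size (%d); pad or reduce k explicitly",
          k, nrow(reference))
  d2 <- pairwise_sqdist(query, reference)
  n <- ncol(d2)
  idx <- seq_len(n)
  out <- matrix(0L, nrow = nrow(d2), ncol = k)
  for (i in seq_len(nrow(d2))) {
    out[i, ] <- order(d2[i, ], idx)[seq_len(k)]
  }
  out
}

#' Farthest point sampling
#'
#' Greedy max-min subset selection used to pick the center points of each
#' network stage. The first selected index is the point farthest from the
#' cloud centroid; every subsequent index maximizes the minimum distance to
#' the already-selected set. All ties are broken by the lexicographically
#' smallest coordinate triple (then smallest index), so the selection is
#' deterministic and invariant to permutations of the input point order.
#'
#' @param cloud N x 3 point matrix.
#' @param m number of points to select, `1 <= m <= N`.
#' @return integer vector of `m` indices into `cloud`, in selection order.
#' @export
farthest_point_sample <- function(cloud, m) {
  validate_cloud(cloud)
  m <- as.integer(m)
  n <- nrow(cloud)
  if (m < 1L) stopf("`m` must be a positive integer")
  if (m > n) stopf("`m` (%d) exceeds the cloud size (%d)", m, n)

  x <- cloud[, 1L]; y <- cloud[, 2L]; z <- cloud[, 3L]
  sqd_to <- function(p) (x - p[1L])^2 + (y - p[2L])^2 + (z - p[3L])^2
  d0 <- sqd_to(c(mean(x), mean(y), mean(z)))
  cand <- which(d0 == max(d0))
  selected <- integer(m)
  selected[1L] <- lex_min_index(cloud, cand)

  if (m > 1L) {
    dmin <- sqd_to(cloud[selected[1L], ])
    for (t in 2L:m) {
      dmin[selected[seq_len(t - 1L)]] <- -Inf # never reselect
      cand <- which(dmin == max(dmin))
      sel <- lex_min_index(cloud, cand)
      selected[t] <- sel
      dmin <- pmin(dmin, sqd_to(cloud[sel, ]))
    }
  }
  selected
}

#' Normalize a point cloud to the unit sphere
#'
#' Centers the cloud at its centroid and scales it so that the farthest
#' point lies at distance 1 from the origin. A degenerate cloud in which all
#' points coincide maps to the all-zero cloud.
#'
#' @param cloud N x 3 point matrix.
#' @return N x 3 matrix with centroid at the origin and maximum norm 1.
#' @export
normalize_unit_sphere <- function(cloud) {
  validate_cloud(cloud)
  centered <- sweep(cloud, 2L, colMeans(cloud))
  r <- sqrt(max(rowSums(centered * centered)))
  if (r == 0) return(centered)
  centered / r
}
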