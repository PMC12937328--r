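# Independent brute-force oracles and tiny shared fixtures.

# Nested-loop Euclidean distances.
oracle_pairwise <- function(query, reference) {
  out <- matrix(0, nrow(query), nrow(reference))
  for (i in seq_len(nrow(query)))
    for (j in seq_len(nrow(reference)))
      out[i, j] <- sqrt(sum((query[i, ] - reference[j, ])^2))
  out
}

# Full-sort KNN with smaller-index tie-break.
oracle_knn <- function(query, reference, k) {
  d <- oracle_pairwise(query, reference)
  t(apply(d, 1L, function(row) order(row, seq_along(row))[seq_len(k)]))
}

# O(N * m * N) greedy farthest point sampling with the same start and
# tie-break rules, written independently of the implementation.
oracle_fps <- function(cloud, m) {
  n <- nrow(cloud)
  lex_pick <- function(cand) {
    cand[order(cloud[cand, 1], cloud[cand, 2], cloud[cand, 3], cand)[1L]]
  }
  centroid <- colMeans(cloud)
  d0 <- sapply(seq_len(n), function(i) sum((cloud[i, ] - centroid)^2))
  sel <- lex_pick(which(d0 == max(d0)))
  while (length(sel) < m) {
    dmin <- sapply(seq_len(n), function(i) {
      if (i %in% sel) return(-Inf)
      min(sapply(sel, function(s) sum((cloud[i, ] - cloud[s, ])^2)))
    })
    sel <- c(sel, lex_pick(which(dmin == max(dmin))))
  }
  sel
}

random_cloud <- function(n, seed = NULL) {
  gen <- function() matrix(stats::rnorm(n * 3), n, 3)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

sample_labels_ <- function(s) vapply(s, `[[`, integer(1), "label")

# A tiny two-stage network configuration used across the network tests.
tiny_model_config <- function(...) {
  model_config(input_points = 32, stage_points = c(16, 8),
               stage_channels = c(8, 16), embedding_channels = 6,
               pre_blocks = 1, pos_blocks = 1, k = 3, num_classes = 4,
               classifier_hidden = 8, dropout = 0, ...)
}

tiny_batch <- function(B = 2, n = 32, seed = 5) {
  withr::with_seed(seed, {
    X <- array(0, c(B, n, 3))
    for (b in seq_len(B)) X[b, , ] <- normalize_unit_sphere(matrix(rnorm(n * 3), n, 3))
    X
  })
}
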