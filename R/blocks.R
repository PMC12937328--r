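# User-facing building blocks. Features use the channel-major ChannelFeature
# convention: a [C x L] matrix for one sample (L = center points at the
# current stage) or a [B, C, L] array for a batch.

#' Partial convolution configuration
#'
#' @param partial_ratio fraction of leading channels that participate in the
#'   convolution; fixed default 1/4.
#' @param kernel_size width of the 1-d convolution; the residual blocks are
#'   pointwise, so only 1 is supported.
#' @export
pconv_config <- function(partial_ratio = 1 / 4, kernel_size = 1) {
  if (partial_ratio <= 0 || partial_ratio > 1)
    stopf("`partial_ratio` must lie in (0, 1]")
  if (as.integer(kernel_size) != 1L)
    stopf("only kernel size 1 (pointwise) convolutions are supported")
  structure(list(partial_ratio = partial_ratio, kernel_size = 1L),
            class = "pconv_config")
}

#' Squeeze-and-excitation configuration
#'
#' @param reduction bottleneck reduction ratio of the excitation MLP
#'   (hidden width = C / reduction, floored, clamped to >= 1); default 8.
#' @export
se_config <- function(reduction = 8) {
  reduction <- as.integer(reduction)
  if (reduction < 1L) stopf("`reduction` must be >= 1")
  structure(list(reduction = reduction), class = "se_config")
}

as_channel_matrix <- function(x) {
  if (is.matrix(x)) return(list(m = x, batched = FALSE, B = 1L))
  d <- dim(x)
  if (length(d) == 3L) {
    m <- matrix(aperm(x, c(2L, 3L, 1L)), nrow = d[2L])
    return(list(m = m, batched = TRUE, B = d[1L], C = d[2L], L = d[3L]))
  }
  stopf("features must be a [C x L] matrix or a [B, C, L] array")
}

restore_channel_shape <- function(m, info) {
  if (!info$batched) return(m)
  aperm(array(m, c(info$C, info$L, info$B)), c(3L, 1L, 2L))
}

#' Initialise partial-convolution weights
#'
#' @param channels input (= output) channel count.
#' @param cfg a [pconv_config()].
#' @param seed optional seed for reproducible initialisation.
#' @return list with `W` (cp x cp) and `b` (cp), cp = ceiling(ratio * C).
#' @export
pconv_weights <- function(channels, cfg = pconv_config(), seed = NULL) {
  init <- function() nn_pconv_init(channels, cfg$partial_ratio)
  if (is.null(seed)) init() else with_seed_preserved(seed, init())
}

#' Partial 1-D convolution
#'
#' Convolves only the first `ceiling(partial_ratio * C)` channels with a
#' pointwise kernel mapping that slice onto itself; all remaining channels
#' are copied bit-identically, retaining the original information at a
#' fraction `partial_ratio^2` of the full convolution's cost. The partial
#' mechanism requires equal input and output channel counts; layers that
#' change the channel count must use a conventional full convolution.
#'
#' @param x features, `[C x L]` matrix or `[B, C, L]` array.
#' @param cfg a [pconv_config()].
#' @param weights list with `W` and `b` as from [pconv_weights()].
#' @return features of the same shape as `x`.
#' @export
pconv1d <- function(x, cfg = pconv_config(), weights) {
  info <- as_channel_matrix(x)
  C <- nrow(info$m)
  cp <- as.integer(ceiling(C * cfg$partial_ratio))
  if (is.null(weights$cp)) weights$cp <- cp
  if (weights$cp != cp || nrow(weights$W) != cp)
    stopf("weights are sized for %d partial channels, configuration expects %d",
          nrow(weights$W), cp)
  restore_channel_shape(nn_pconv_fwd(weights, info$m), info)
}

#' Initialise the weights of a partial-convolution residual block
#'
#' @inheritParams pconv_weights
#' @export
pconv_resblock_weights <- function(channels, cfg = pconv_config(), seed = NULL) {
  init <- function() resblock_init(channels, cfg$partial_ratio)
  if (is.null(seed)) init() else with_seed_preserved(seed, init())
}

#' Partial-convolution residual block
#'
#' Two cascaded partial pointwise convolutions, each followed by batch
#' normalisation, with a ReLU between them; the result is added to the input
#' through a skip connection and passed through a final ReLU:
#' `y = relu(x + bn2(pconv(relu(bn1(pconv(x))))))`.
#'
#' @inheritParams pconv1d
#' @param weights as from [pconv_resblock_weights()].
#' @param train logical; `TRUE` uses batch statistics in the normalisation
#'   layers, `FALSE` the stored running statistics.
#' @return features of the same shape as `x`.
#' @export
pconv_resblock <- function(x, cfg = pconv_config(), weights, train = FALSE) {
  info <- as_channel_matrix(x)
  out <- resblock_fwd(weights$par, weights$buf, info$m, train = train,
                      partial = weights$partial)
  restore_channel_shape(out$y, info)
}

#' Initialise squeeze-and-excitation weights
#'
#' @param channels channel count C.
#' @param cfg a [se_config()].
#' @param seed optional seed.
#' @export
se_weights <- function(channels, cfg = se_config(), seed = NULL) {
  init <- function() se_init(channels, cfg$reduction)
  if (is.null(seed)) init() else with_seed_preserved(seed, init())
}

#' Squeeze-and-excitation channel attention
#'
#' Squeeze: global average pooling over the length dimension gives one
#' C-vector per sample. Excitation: `sigmoid(FC2(relu(FC1(z))))` with the
#' bottleneck `C -> C/reduction -> C`. Re-scale: the input is multiplied
#' channel-wise by the resulting gates, which lie strictly inside (0, 1).
#'
#' @inheritParams pconv1d
#' @param cfg a [se_config()].
#' @param weights list with `fc1`, `fc2` as from [se_weights()].
#' @return features of the same shape as `x`.
#' @export
se_block <- function(x, cfg = se_config(), weights) {
  info <- as_channel_matrix(x)
  L <- ncol(info$m) / info$B
  out <- se_fwd(weights, info$m, B = info$B, S = as.integer(L))
  restore_channel_shape(out$y, info)
}

#' Geometric affine normalisation of a grouped neighborhood
#'
#' Normalizes the residuals between each neighbor feature and its center
#' feature by the per-group standard deviation (computed over all channels
#' and neighbors of the group, epsilon-stabilised), then applies a learnable
#' per-channel affine transform `alpha * r / (sd + eps) + beta`. The output
#' shape equals the input shape; a constant group (zero variance) yields a
#' finite output.
#'
#' @param grouped a [grouped_neighborhood()].
#' @param alpha,beta numeric vectors of length C (channel count).
#' @param center_features optional `[B, S, C]` array of center features; when
#'   omitted, the first neighbor slot (the center itself under
#'   self-inclusion) is used.
#' @param eps stabiliser added to the group standard deviation.
#' @return a [grouped_neighborhood()] with normalized features.
#' @export
geometric_affine <- function(grouped, alpha, beta, center_features = NULL,
                             eps = 1e-5) {
  stopifnot(inherits(grouped, "grouped_neighborhood"))
  d <- dim(grouped$features)
  B <- d[1L]; S <- d[2L]; K <- d[3L]; C <- d[4L]
  if (length(alpha) != C || length(beta) != C)
    stopf("`alpha` and `beta` must have length %d (channels)", C)
  out <- grouped$features
  par <- list(a = alpha, b = beta)
  for (b in seq_len(B)) {
    gn <- matrix(aperm(grouped$features[b, , , , drop = FALSE], c(4L, 3L, 2L, 1L)),
                 nrow = C)
    if (is.null(center_features)) {
      fc <- gn[, seq(1L, by = K, length.out = S), drop = FALSE]
    } else {
      fc <- matrix(aperm(center_features[b, , , drop = FALSE], c(3L, 2L, 1L)),
                   nrow = C)
    }
    fc_rep <- fc[, rep(seq_len(S), each = K), drop = FALSE]
    y <- affine_fwd(par, gn, fc_rep, K = K, eps = eps)$y
    out[b, , , ] <- aperm(array(y, c(C, K, S)), c(3L, 2L, 1L))
  }
  grouped$features <- out
  grouped
}
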