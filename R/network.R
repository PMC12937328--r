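# The full classification network: a four-stage residual point-MLP backbone
# in which every stage (i) picks center points by farthest point sampling,
# (ii) groups neighbors with the dual-branch standard/dilated KNN module,
# (iii) normalizes grouped features with a learnable geometric affine,
# (iv) transforms per-neighbor edge features with a shared MLP and residual
# blocks and max-pools across neighbors, (v) recalibrates channels with a
# squeeze-and-excitation gate, and (vi) refines center features with further
# residual blocks. A global-average-pooled embedding feeds a small fully
# connected classifier.

#' Network configuration
#'
#' The default configuration follows the residual point-MLP backbone lineage: a
#' 64-channel embedding with channel doubling per stage
#' (128/256/512/1024), stage center counts halving from the input point
#' count, two residual blocks in each of the pre- and pos-extraction
#' branches per stage, 24 neighbors per branch, SE reduction 8 and partial
#' ratio 1/4. This is the configuration whose analytic complexity profile
#' matches the reference complexity figures for this architecture (see the methods
#' vignette for the calibration).
#'
#' @param input_points points per input cloud.
#' @param stage_points center counts per stage; default halves the input
#'   point count at every stage.
#' @param stage_channels output channels per stage; default doubles the
#'   embedding width at every stage.
#' @param embedding_channels width of the shared pointwise embedding applied
#'   before stage 1.
#' @param pre_blocks,pos_blocks residual blocks in the pre-extraction
#'   (per-neighbor, before max-pooling) and pos-extraction (per-center)
#'   branches of every stage.
#' @param k neighbors per grouping branch (the fused neighborhood has 2k).
#' @param se_reduction SE bottleneck reduction ratio.
#' @param partial_ratio partial-convolution channel fraction.
#' @param num_classes number of individuals to discriminate.
#' @param classifier_hidden hidden widths of the classifier head.
#' @param dropout dropout probability between classifier layers.
#' @param jitter_delta training-time query jitter of the dilated branch.
#' @param rng_seed seed of the dedicated evaluation-time generator for the
#'   stochastic dilated sampling.
#' @param variant `"baseline"` (single-branch KNN grouping, conventional
#'   residual blocks, no SE), `"dlf_only"` (dual-branch grouping added) or
#'   `"full"` (dual-branch grouping plus partial convolutions and SE).
#' @return a list of class `model_config`.
#' @export
model_config <- function(input_points = 1024,
                         stage_points = NULL,
                         stage_channels = NULL,
                         embedding_channels = 64,
                         pre_blocks = 2,
                         pos_blocks = 2,
                         k = 24,
                         se_reduction = 8,
                         partial_ratio = 1 / 4,
                         num_classes = 10,
                         classifier_hidden = c(512, 256),
                         dropout = 0.5,
                         jitter_delta = 0.2,
                         rng_seed = 42,
                         variant = c("full", "baseline", "dlf_only")) {
  variant <- match.arg(variant)
  n_stages <- if (!is.null(stage_points)) length(stage_points)
              else if (!is.null(stage_channels)) length(stage_channels)
              else 4L
  if (is.null(stage_points))
    stage_points <- as.integer(input_points / 2^seq_len(n_stages))
  if (is.null(stage_channels))
    stage_channels <- as.integer(embedding_channels * 2^seq_len(n_stages))
  stage_points <- as.integer(stage_points)
  stage_channels <- as.integer(stage_channels)
  if (length(stage_points) != length(stage_channels))
    stopf("`stage_points` and `stage_channels` must have equal length")
  if (any(diff(stage_points) >= 0))
    stopf("`stage_points` must be strictly decreasing")
  if (stage_points[1L] > input_points)
    stopf("`stage_points[1]` must not exceed `input_points`")
  if (dropout < 0 || dropout >= 1) stopf("`dropout` must lie in [0, 1)")
  if (partial_ratio <= 0 || partial_ratio > 1)
    stopf("`partial_ratio` must lie in (0, 1]")
  structure(list(
    input_points = as.integer(input_points),
    stage_points = stage_points,
    stage_channels = stage_channels,
    embedding_channels = as.integer(embedding_channels),
    pre_blocks = as.integer(pre_blocks),
    pos_blocks = as.integer(pos_blocks),
    k = as.integer(k),
    se_reduction = as.integer(se_reduction),
    partial_ratio = partial_ratio,
    num_classes = as.integer(num_classes),
    classifier_hidden = as.integer(classifier_hidden),
    dropout = dropout,
    jitter_delta = jitter_delta,
    rng_seed = as.integer(rng_seed),
    variant = variant
  ), class = "model_config")
}

stage_group_size <- function(cfg) {
  if (cfg$variant == "baseline") cfg$k else 2L * cfg$k
}

uses_se <- function(cfg) cfg$variant == "full"

uses_pconv <- function(cfg) cfg$variant == "full"

uses_dlf <- function(cfg) cfg$variant != "baseline"

#' Build a network from a configuration
#'
#' @param cfg a [model_config()].
#' @param seed seed for reproducible weight initialisation.
#' @return an object of class `dk_model` holding the configuration, the
#'   trainable parameters and the batch-normalisation running statistics.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed_preserved(seed, {
    ns <- length(cfg$stage_points)
    pratio <- if (uses_pconv(cfg)) cfg$partial_ratio else NULL
    par <- list(); buf <- list()
    C0 <- cfg$embedding_channels
    par$embed <- list(lin = nn_linear_init(3L, C0), bn = nn_bn_init(C0))
    buf$embed <- list(bn = nn_bn_buf_init(C0))
    cin <- C0
    par$stages <- vector("list", ns)
    buf$stages <- vector("list", ns)
    for (i in seq_len(ns)) {
      cout <- cfg$stage_channels[i]
      sp <- list(affine = list(a = rep(1, cin), b = numeric(cin)),
                 transfer = list(lin = nn_linear_init(2L * cin + 3L, cout),
                                 bn = nn_bn_init(cout)))
      sb <- list(transfer = list(bn = nn_bn_buf_init(cout)))
      sp$pre <- vector("list", cfg$pre_blocks)
      sb$pre <- vector("list", cfg$pre_blocks)
      for (j in seq_len(cfg$pre_blocks)) {
        rb <- resblock_init(cout, pratio)
        sp$pre[[j]] <- rb$par; sb$pre[[j]] <- rb$buf
      }
      if (uses_se(cfg)) sp$se <- se_init(cout, cfg$se_reduction)
      sp$pos <- vector("list", cfg$pos_blocks)
      sb$pos <- vector("list", cfg$pos_blocks)
      for (j in seq_len(cfg$pos_blocks)) {
        rb <- resblock_init(cout, pratio)
        sp$pos[[j]] <- rb$par; sb$pos[[j]] <- rb$buf
      }
      par$stages[[i]] <- sp
      buf$stages[[i]] <- sb
      cin <- cout
    }
    widths <- c(cin, cfg$classifier_hidden)
    par$cls <- list(hidden = vector("list", length(cfg$classifier_hidden)))
    buf$cls <- list(hidden = vector("list", length(cfg$classifier_hidden)))
    for (h in seq_along(cfg$classifier_hidden)) {
      par$cls$hidden[[h]] <- list(lin = nn_linear_init(widths[h], widths[h + 1L]),
                                  bn = nn_bn_init(widths[h + 1L]))
      buf$cls$hidden[[h]] <- list(bn = nn_bn_buf_init(widths[h + 1L]))
    }
    par$cls$out <- nn_linear_init(widths[length(widths)], cfg$num_classes)
    structure(list(cfg = cfg, par = par, buf = buf), class = "dk_model")
  })
}

#' @export
print.dk_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<dk_model> variant=%s | %d stages | input %d pts | k=%d | %s params\n",
              cfg$variant, length(cfg$stage_points), cfg$input_points, cfg$k,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

as_batch_array <- function(X) {
  if (is.list(X)) {
    n <- nrow(X[[1L]])
    A <- array(0, c(length(X), n, 3L))
    for (b in seq_along(X)) A[b, , ] <- X[[b]]
    return(A)
  }
  if (is.matrix(X)) {
    A <- array(0, c(1L, nrow(X), 3L))
    A[1L, , ] <- X
    return(A)
  }
  X
}

# Full forward pass. Returns logits plus (optionally) the activation caches
# needed for the analytic backward pass and the updated BN running buffers.
dk_forward <- function(model, X, train = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg; par <- model$par; buf <- model$buf
  X <- as_batch_array(X)
  B <- dim(X)[1L]; N <- dim(X)[2L]
  if (N != cfg$input_points)
    stopf("input clouds have %d points; the model expects %d (resample first)",
          N, cfg$input_points)
  cache <- if (keep_cache) list(B = B) else NULL

  P <- matrix(aperm(X, c(3L, 2L, 1L)), nrow = 3L) # [3 x B*N]
  e1 <- nn_linear_fwd(par$embed$lin, P)
  eb <- nn_bn_fwd(par$embed$bn, buf$embed$bn, e1, train)
  er <- nn_relu_fwd(eb$y)
  newbuf <- buf
  newbuf$embed$bn <- eb$buf
  if (keep_cache) cache$embed <- list(x = P, bn = eb$cache, mask = er$mask)

  FT <- er$y
  xyz <- P
  Ncur <- N
  ns <- length(cfg$stage_points)
  Kg <- stage_group_size(cfg)
  if (keep_cache) cache$stages <- vector("list", ns)

  for (i in seq_len(ns)) {
    S <- cfg$stage_points[i]
    Cin <- nrow(FT)
    sp <- par$stages[[i]]; sb <- newbuf$stages[[i]]
    gidx <- integer(B * S * Kg)
    cidx <- integer(B * S)
    for (b in seq_len(B)) {
      cols <- (b - 1L) * Ncur + seq_len(Ncur)
      xb <- t(xyz[, cols, drop = FALSE])
      ctr <- farthest_point_sample(xb, S)
      std <- knn_indices(xb[ctr, , drop = FALSE], xb, cfg$k)
      if (uses_dlf(cfg)) {
        q <- xb[ctr, , drop = FALSE]
        if (train) {
          if (cfg$jitter_delta > 0)
            q <- q + matrix(stats::runif(length(q), -cfg$jitter_delta,
                                         cfg$jitter_delta), nrow(q), 3L)
          dil <- dilated_indices(xb, q, cfg$k)
        } else {
          # evaluation: a dedicated generator re-seeded identically for
          # every sample of a stage, so results are reproducible and
          # independent of batch composition and position
          dil <- with_seed_preserved(derive_seed(cfg$rng_seed, 8L, i),
                                     dilated_indices(xb, q, cfg$k))
        }
        fused <- cbind(std, dil)
      } else {
        fused <- std
      }
      gidx[(b - 1L) * S * Kg + seq_len(S * Kg)] <- (b - 1L) * Ncur + as.vector(t(fused))
      cidx[(b - 1L) * S + seq_len(S)] <- (b - 1L) * Ncur + ctr
    }
    rep_idx <- rep(seq_len(B * S), each = Kg)
    Gn <- FT[, gidx, drop = FALSE]
    Fc <- FT[, cidx, drop = FALSE]
    Fc_rep <- Fc[, rep_idx, drop = FALSE]
    cxyz <- xyz[, cidx, drop = FALSE]
    relxyz <- xyz[, gidx, drop = FALSE] - cxyz[, rep_idx, drop = FALSE]

    af <- affine_fwd(sp$affine, Gn, Fc_rep, K = Kg)
    E <- rbind(Fc_rep, af$y, relxyz)
    t1 <- nn_linear_fwd(sp$transfer$lin, E)
    tb <- nn_bn_fwd(sp$transfer$bn, sb$transfer$bn, t1, train)
    tr <- nn_relu_fwd(tb$y)
    newbuf$stages[[i]]$transfer$bn <- tb$buf
    H <- tr$y

    pre_caches <- vector("list", cfg$pre_blocks)
    for (j in seq_len(cfg$pre_blocks)) {
      rb <- resblock_fwd(sp$pre[[j]], sb$pre[[j]], H, train, uses_pconv(cfg))
      newbuf$stages[[i]]$pre[[j]] <- rb$buf
      if (keep_cache) pre_caches[[j]] <- rb$cache
      H <- rb$y
    }
    mp <- maxpool_fwd(H, Kg)
    Hp <- mp$y
    se_cache <- NULL
    if (uses_se(cfg)) {
      sef <- se_fwd(sp$se, Hp, B = B, S = S)
      if (keep_cache) se_cache <- sef$cache
      Hp <- sef$y
    }
    pos_caches <- vector("list", cfg$pos_blocks)
    for (j in seq_len(cfg$pos_blocks)) {
      rb <- resblock_fwd(sp$pos[[j]], sb$pos[[j]], Hp, train, uses_pconv(cfg))
      newbuf$stages[[i]]$pos[[j]] <- rb$buf
      if (keep_cache) pos_caches[[j]] <- rb$cache
      Hp <- rb$y
    }
    if (keep_cache) {
      cache$stages[[i]] <- list(
        gidx = gidx, cidx = cidx, rep_idx = rep_idx, Ncur = Ncur, S = S,
        Cin = Cin, Kg = Kg, E = E, affine = af$cache,
        bn = tb$cache, mask = tr$mask, pre = pre_caches, mp = mp,
        se = se_cache, pos = pos_caches)
    }
    FT <- Hp
    xyz <- cxyz
    Ncur <- S
  }

  Slast <- Ncur
  Clast <- nrow(FT)
  G <- matrix(0, Clast, B)
  for (b in seq_len(B)) {
    cols <- (b - 1L) * Slast + seq_len(Slast)
    G[, b] <- rowMeans(FT[, cols, drop = FALSE])
  }
  if (keep_cache) cache$gap <- list(Slast = Slast, Clast = Clast)

  H <- G
  nh <- length(cfg$classifier_hidden)
  cls_caches <- vector("list", nh)
  for (h in seq_len(nh)) {
    hp <- par$cls$hidden[[h]]; hb <- newbuf$cls$hidden[[h]]
    l1 <- nn_linear_fwd(hp$lin, H)
    b1 <- nn_bn_fwd(hp$bn, hb$bn, l1, train)
    r1 <- nn_relu_fwd(b1$y)
    newbuf$cls$hidden[[h]]$bn <- b1$buf
    y <- r1$y
    dmask <- NULL
    if (train && cfg$dropout > 0) {
      dmask <- matrix(stats::runif(length(y)) >= cfg$dropout, nrow(y), ncol(y)) /
        (1 - cfg$dropout)
      y <- y * dmask
    }
    if (keep_cache) cls_caches[[h]] <- list(x = H, bn = b1$cache,
                                            mask = r1$mask, dmask = dmask)
    H <- y
  }
  logits <- nn_linear_fwd(par$cls$out, H)
  if (keep_cache) {
    cache$cls <- cls_caches
    cache$cls_out_x <- H
  }
  list(logits = t(logits), cache = cache, buf = newbuf)
}

# Analytic backward pass; `fw` is the result of dk_forward(keep_cache=TRUE).
# dlogits is [B x num_classes]. Returns a gradient tree shaped like par.
dk_backward <- function(model, fw, dlogits) {
  cfg <- model$cfg; par <- model$par; cache <- fw$cache
  train <- TRUE
  B <- cache$B
  g <- list()

  dout <- t(dlogits)
  go <- nn_linear_bwd(par$cls$out, cache$cls_out_x, dout)
  g$cls <- list(out = list(W = go$dW, b = go$db),
                hidden = vector("list", length(cfg$classifier_hidden)))
  dH <- go$dx
  for (h in rev(seq_along(cfg$classifier_hidden))) {
    cc <- cache$cls[[h]]
    if (!is.null(cc$dmask)) dH <- dH * cc$dmask
    dr <- nn_relu_bwd(cc$mask, dH)
    gb <- nn_bn_bwd(par$cls$hidden[[h]]$bn, cc$bn, dr, train)
    gl <- nn_linear_bwd(par$cls$hidden[[h]]$lin, cc$x, gb$dx)
    g$cls$hidden[[h]] <- list(lin = list(W = gl$dW, b = gl$db),
                              bn = list(g = gb$dg, b = gb$db))
    dH <- gl$dx
  }

  Slast <- cache$gap$Slast
  dF <- dH[, rep(seq_len(B), each = Slast), drop = FALSE] / Slast

  ns <- length(cfg$stage_points)
  g$stages <- vector("list", ns)
  for (i in rev(seq_len(ns))) {
    sc <- cache$stages[[i]]
    sp <- par$stages[[i]]
    gs <- list()

    for (j in rev(seq_len(cfg$pos_blocks))) {
      rb <- resblock_bwd(sp$pos[[j]], sc$pos[[j]], dF, train, uses_pconv(cfg))
      gs$pos[[j]] <- rb$grads
      dF <- rb$dx
    }
    if (uses_se(cfg)) {
      seb <- se_bwd(sp$se, sc$se, dF)
      gs$se <- seb$grads
      dF <- seb$dx
    }
    dHpre <- maxpool_bwd(sc$mp, dF)
    for (j in rev(seq_len(cfg$pre_blocks))) {
      rb <- resblock_bwd(sp$pre[[j]], sc$pre[[j]], dHpre, train, uses_pconv(cfg))
      gs$pre[[j]] <- rb$grads
      dHpre <- rb$dx
    }
    dtr <- nn_relu_bwd(sc$mask, dHpre)
    gbn <- nn_bn_bwd(sp$transfer$bn, sc$bn, dtr, train)
    glin <- nn_linear_bwd(sp$transfer$lin, sc$E, gbn$dx)
    gs$transfer <- list(lin = list(W = glin$dW, b = glin$db),
                        bn = list(g = gbn$dg, b = gbn$db))
    dE <- glin$dx

    Cin <- sc$Cin
    dFc_rep <- dE[seq_len(Cin), , drop = FALSE]
    dGn_hat <- dE[Cin + seq_len(Cin), , drop = FALSE]
    ab <- affine_bwd(sp$affine, sc$affine, dGn_hat)
    gs$affine <- ab$grads
    dGn <- ab$dgn
    dFc_rep <- dFc_rep + ab$dfc_rep
    # collapse the Kg replicated center columns
    Kg <- sc$Kg
    dFc <- rowsum_channels(dFc_rep, Cin, Kg)

    dF <- scatter_add_cols(Cin, B * sc$Ncur, dGn, sc$gidx) +
      scatter_add_cols(Cin, B * sc$Ncur, dFc, sc$cidx)
    g$stages[[i]] <- gs
  }

  dr <- nn_relu_bwd(cache$embed$mask, dF)
  gb <- nn_bn_bwd(par$embed$bn, cache$embed$bn, dr, train)
  gl <- nn_linear_bwd(par$embed$lin, cache$embed$x, gb$dx)
  g$embed <- list(lin = list(W = gl$dW, b = gl$db),
                  bn = list(g = gb$dg, b = gb$db))
  g
}

# Sum Kg consecutive column-blocks: [C x M*Kg] -> [C x M].
rowsum_channels <- function(x, C, Kg) {
  M <- ncol(x) %/% Kg
  A <- matrix(x, nrow = C * Kg) # [C*Kg x M], neighbor-major rows
  out <- rowsum(A, group = rep(seq_len(C), times = Kg))
  out
}

#' Forward pass to class logits
#'
#' @param object a built `dk_model`.
#' @param ... passed to methods.
#' @return `[B x num_classes]` matrix of logits.
#' @export
forward <- function(object, ...) UseMethod("forward")

#' @rdname forward
#' @param batch `[B, N, 3]` array, a single N x 3 cloud, or a list of clouds,
#'   each normalized to the unit sphere with exactly `input_points` points.
#' @param mode `"eval"` (deterministic: BN running statistics, no dropout,
#'   dilated sampling from a dedicated generator re-seeded from the model's
#'   `rng_seed` at the start of the pass) or `"train"` (batch statistics,
#'   dropout, stochastic grouping from the current RNG stream).
#' @export
forward.dk_model <- function(object, batch, mode = c("eval", "train"), ...) {
  mode <- match.arg(mode)
  if (mode == "eval") {
    with_seed_preserved(object$cfg$rng_seed,
                        dk_forward(object, batch, train = FALSE)$logits)
  } else {
    dk_forward(object, batch, train = TRUE)$logits
  }
}

#' @export
predict.dk_model <- function(object, newdata, ...) {
  lg <- forward(object, newdata, mode = "eval")
  max.col(lg, ties.method = "first")
}

# ---- complexity profiling ------------------------------------------------

flat_params <- function(x) {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      if (identical(nm, "cp")) next
      out <- c(out, flat_params(x[[nm]]))
    }
    if (is.null(names(x))) for (el in x) out <- c(out, flat_params(el))
    return(out)
  }
  if (is.numeric(x)) list(x) else list()
}

#' Count trainable parameters
#'
#' Counts every trainable scalar (weights, biases, batch-norm scales/shifts,
#' affine alpha/beta, SE weights); running statistics are buffers, not
#' parameters.
#'
#' @param model a `dk_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(flat_params(model$par), length, integer(1)))
}

#' Analytic FLOPs count for one sample's forward pass
#'
#' Layer-wise closed-form count with the convention that one
#' multiply-accumulate equals 2 FLOPs. By default only convolutions and
#' fully connected layers are counted (batch normalisation, activations,
#' pooling and the affine normalisation are excluded); set
#' `include_elementwise = TRUE` to add an estimate of those elementwise
#' operations. Neighbor search and farthest point sampling are data
#' reorganisation, not counted. When `n_points` differs from the configured
#' input size, stage center counts are scaled proportionally (the halving
#' schedule), which is how the profiler reports multiple resolutions for one
#' architecture.
#'
#' @param model a `dk_model`.
#' @param n_points profiling resolution (input points per sample).
#' @param include_elementwise also count elementwise operations.
#' @return FLOPs per sample, as a double.
#' @export
count_flops <- function(model, n_points = model$cfg$input_points,
                        include_elementwise = FALSE) {
  cfg <- model$cfg
  ratio <- n_points / cfg$input_points
  centers <- round(cfg$stage_points * ratio)
  Kg <- stage_group_size(cfg)
  pc <- uses_pconv(cfg)
  fl <- 0
  elw <- 0
  C0 <- cfg$embedding_channels
  fl <- fl + 2 * 3 * C0 * n_points
  elw <- elw + 3 * C0 * n_points # BN (2) + ReLU (1)
  cin <- C0
  for (i in seq_along(centers)) {
    S <- centers[i]
    cout <- cfg$stage_channels[i]
    elem <- S * Kg
    fl <- fl + 2 * (2 * cin + 3) * cout * elem # transfer
    convw <- if (pc) as.integer(ceiling(cout * cfg$partial_ratio))^2 else cout^2
    fl <- fl + cfg$pre_blocks * 2 * 2 * convw * elem # two convs per block
    fl <- fl + cfg$pos_blocks * 2 * 2 * convw * S
    if (uses_se(cfg)) {
      h <- max(1L, cout %/% cfg$se_reduction)
      fl <- fl + 2 * cout * h * 2
    }
    if (include_elementwise) {
      elw <- elw + 4 * cin * elem # affine normalisation
      elw <- elw + 3 * cout * elem # transfer BN + ReLU
      elw <- elw + cfg$pre_blocks * (2 * 3 * cout * elem + 2 * cout * elem)
      elw <- elw + cout * (Kg - 1) * S # max-pool comparisons
      if (uses_se(cfg)) elw <- elw + cout * S + cout * S # squeeze + rescale
      elw <- elw + cfg$pos_blocks * (2 * 3 * cout * S + 2 * cout * S)
    }
    cin <- cout
  }
  widths <- c(cin, cfg$classifier_hidden, cfg$num_classes)
  fl <- fl + sum(2 * widths[-length(widths)] * widths[-1L])
  if (include_elementwise) {
    elw <- elw + cin * centers[length(centers)] # global average pooling
    fl <- fl + elw
  }
  fl
}

#' Profile a configuration's parameters and FLOPs
#'
#' @param cfg a [model_config()].
#' @param resolutions input point counts at which FLOPs are reported.
#' @return data.frame with variant, parameter count, and one FLOPs column
#'   per resolution.
#' @export
profile_model <- function(cfg, resolutions = c(1024, 2048)) {
  model <- build_model(cfg, seed = 1L)
  out <- data.frame(variant = cfg$variant,
                    params = count_parameters(model))
  for (r in resolutions)
    out[[sprintf("flops_%d", r)]] <- count_flops(model, n_points = r)
  out
}

# ---- serialisation -------------------------------------------------------

#' Save a model as a weights file plus a plain-text YAML configuration
#'
#' @param model a `dk_model`.
#' @param weights_path destination for the serialized weights (RDS).
#' @param config_path destination for the YAML configuration dump; defaults
#'   to `<weights_path>.yaml`.
#' @return `weights_path`, invisibly.
#' @export
save_model <- function(model, weights_path,
                       config_path = paste0(weights_path, ".yaml")) {
  saveRDS(list(par = model$par, buf = model$buf), weights_path)
  yaml::write_yaml(unclass(model$cfg), config_path)
  invisible(weights_path)
}

#' Load a model saved by [save_model()]
#'
#' @inheritParams save_model
#' @return a `dk_model`.
#' @export
load_model <- function(weights_path,
                       config_path = paste0(weights_path, ".yaml")) {
  cfgl <- yaml::read_yaml(config_path)
  cfg <- do.call(model_config, cfgl[setdiff(names(cfgl), character(0))])
  w <- readRDS(weights_path)
  structure(list(cfg = cfg, par = w$par, buf = w$buf), class = "dk_model")
}
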