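# Training loop: SGD with momentum, cosine learning-rate annealing,
# label-smoothed cross-entropy, early stopping on validation overall
# accuracy, plus the ablation and neighborhood-size sweep runners.

#' Training configuration
#'
#' Defaults follow the standard recipe for this architecture: SGD with momentum 0.9 (Nesterov
#' off), initial learning rate 0.0015 annealed cosine-wise to 1e-5, weight
#' decay 5e-4, batch size 16, at most 150 epochs with early stopping after
#' 20 epochs without validation improvement, and label smoothing 0.1.
#'
#' @param lr0 initial learning rate.
#' @param lr_min annealing floor.
#' @param momentum SGD momentum.
#' @param nesterov use Nesterov acceleration.
#' @param weight_decay L2 weight decay coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without a new best validation OA before
#'   training halts.
#' @param label_smoothing label smoothing factor of the cross-entropy loss.
#' @param val_fraction session-level fraction of the training set kept for
#'   training when no validation set is supplied (the remainder becomes the
#'   validation fold).
#' @param seed master seed; shuffling, augmentation and stochastic grouping
#'   derive per-epoch/per-batch child seeds from it.
#' @return a list of class `train_config`.
#' @export
train_config <- function(lr0 = 0.0015, lr_min = 1e-5, momentum = 0.9,
                         nesterov = FALSE, weight_decay = 5e-4,
                         batch_size = 16, max_epochs = 150,
                         early_stop_patience = 20, label_smoothing = 0.1,
                         val_fraction = 0.9, seed = 42) {
  if (lr_min >= lr0) stopf("`lr_min` must be smaller than `lr0`")
  if (early_stop_patience >= max_epochs)
    stopf("`early_stop_patience` must be smaller than `max_epochs`")
  structure(list(lr0 = lr0, lr_min = lr_min, momentum = momentum,
                 nesterov = nesterov, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 label_smoothing = label_smoothing,
                 val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `lr = lr_min + (lr0 - lr_min) * (1 + cos(pi * epoch / max_epochs)) / 2`,
#' stepped once per epoch (0-based).
#'
#' @param epoch epoch index in `0..max_epochs`.
#' @param cfg a [train_config()].
#' @return the learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg$max_epochs)
    stopf("`epoch` must lie in [0, %d]", cfg$max_epochs)
  cfg$lr_min + (cfg$lr0 - cfg$lr_min) * (1 + cos(pi * epoch / cfg$max_epochs)) / 2
}

# Label-smoothed cross-entropy; logits [B x C], labels in 1..C.
# Returns the mean loss and its gradient w.r.t. the logits.
ce_loss_smoothed <- function(logits, labels, smoothing) {
  B <- nrow(logits); C <- ncol(logits)
  m <- apply(logits, 1L, max)
  z <- logits - m
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  target <- matrix(smoothing / C, B, C)
  target[cbind(seq_len(B), labels)] <- target[cbind(seq_len(B), labels)] +
    (1 - smoothing)
  loss <- -sum(target * logp) / B
  p <- exp(logp)
  dlogits <- (p - target) / B
  list(loss = loss, dlogits = dlogits)
}

# Early-stopping rule: halt once `patience` epochs have elapsed since the
# last strict improvement of the validation OA.
should_stop <- function(epoch, best_epoch, patience) {
  epoch - best_epoch >= patience
}

# SGD with momentum / Nesterov and L2 weight decay over a parameter tree.
sgd_step <- function(par, grads, state, lr, momentum, weight_decay, nesterov) {
  if (is.list(par)) {
    for (nm in names(par)) {
      if (identical(nm, "cp")) next
      sub <- sgd_step(par[[nm]], grads[[nm]], state[[nm]], lr, momentum,
                      weight_decay, nesterov)
      par[[nm]] <- sub$par
      state[[nm]] <- sub$state
    }
    return(list(par = par, state = state))
  }
  g <- grads + weight_decay * par
  v <- if (is.null(state)) g else momentum * state + g
  step <- if (nesterov) g + momentum * v else v
  list(par = par - lr * step, state = v)
}

#' Prepare samples for the network
#'
#' Resamples every cloud to the model's input point count (uniformly,
#' without replacement when possible) and normalizes it to the unit sphere.
#'
#' @param samples list of [pc_sample()] objects.
#' @param n_points target point count.
#' @param seed seed controlling the resampling.
#' @return list of [pc_sample()] objects with n_points-sized unit-sphere clouds.
#' @export
prepare_dataset <- function(samples, n_points, seed = 42) {
  lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    s$cloud <- normalize_unit_sphere(
      resample_fixed(s$cloud, n_points, seed = derive_seed(seed, 4L, i)))
    s
  })
}

#' Train a model
#'
#' Minibatch SGD with the label-smoothed cross-entropy loss, per-epoch
#' cosine annealing, per-epoch reshuffling and augmentation, validation
#' after every epoch, and early stopping that restores the
#' best-validation-OA weights. All stochastic components (shuffling,
#' augmentation, dropout, dilated neighbor sampling) draw from child seeds
#' derived deterministically from `(seed, epoch, batch)`, so a run is fully
#' reproducible while still varying across epochs.
#'
#' @param model a freshly built `dk_model`.
#' @param train_samples list of prepared [pc_sample()] objects (see
#'   [prepare_dataset()]).
#' @param val_samples optional validation list; when `NULL`, a session-level
#'   fold is carved from `train_samples` so no recording session spans both
#'   sides.
#' @param cfg a [train_config()].
#' @param augment apply the scale/translate/shuffle augmentation during
#'   training.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best weights), `history` (data.frame with
#'   epoch, lr, train_loss, val_oa), `best_epoch` and `best_val_oa`.
#' @export
train_model <- function(model, train_samples, val_samples = NULL,
                        cfg = train_config(), augment = TRUE, verbose = FALSE) {
  if (!length(train_samples)) stopf("`train_samples` is empty")
  if (is.null(val_samples)) {
    sp <- video_level_split(train_samples, train_fraction = cfg$val_fraction,
                            seed = derive_seed(cfg$seed, 5L))
    train_samples <- sp$train
    val_samples <- sp$test
    if (!length(val_samples))
      stopf("could not carve a validation fold; supply `val_samples`")
  }
  labels <- sample_labels(train_samples)
  state <- NULL
  best <- list(oa = -Inf, epoch = -1L, par = model$par, buf = model$buf)
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_oa = numeric(0))
  for (epoch in 0:(cfg$max_epochs - 1L)) {
    lr <- cosine_lr(epoch, cfg)
    ord <- with_seed_preserved(derive_seed(cfg$seed, 6L, epoch),
                               sample.int(length(train_samples)))
    starts <- seq(1L, length(ord), by = cfg$batch_size)
    epoch_loss <- 0
    nb <- 0L
    for (bi in seq_along(starts)) {
      ix <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, length(ord))]
      step <- with_seed_preserved(derive_seed(cfg$seed, 7L, epoch, bi), {
        clouds <- lapply(train_samples[ix], `[[`, "cloud")
        if (augment) clouds <- lapply(clouds, augment_cloud)
        fw <- dk_forward(model, clouds, train = TRUE, keep_cache = TRUE)
        ls <- ce_loss_smoothed(fw$logits, labels[ix], cfg$label_smoothing)
        if (!is.finite(ls$loss))
          stopf("non-finite loss at epoch %d, batch %d; lower the learning rate",
                epoch, bi)
        grads <- dk_backward(model, fw, ls$dlogits)
        list(loss = ls$loss, grads = grads, buf = fw$buf)
      })
      model$buf <- step$buf
      upd <- sgd_step(model$par, step$grads, state, lr, cfg$momentum,
                      cfg$weight_decay, cfg$nesterov)
      model$par <- upd$par
      state <- upd$state
      epoch_loss <- epoch_loss + step$loss
      nb <- nb + 1L
    }
    val <- evaluate_model(model, val_samples, batch_size = cfg$batch_size)
    history <- rbind(history,
                     data.frame(epoch = epoch, lr = lr,
                                train_loss = epoch_loss / nb, val_oa = val$oa))
    if (verbose)
      message(sprintf("epoch %3d | lr %.5f | loss %.4f | val OA %.4f",
                      epoch, lr, epoch_loss / nb, val$oa))
    if (val$oa > best$oa) {
      best <- list(oa = val$oa, epoch = epoch, par = model$par, buf = model$buf)
    } else if (should_stop(epoch, best$epoch, cfg$early_stop_patience)) {
      break
    }
  }
  model$par <- best$par
  model$buf <- best$buf
  list(model = model, history = history,
       best_epoch = best$epoch, best_val_oa = best$oa)
}

dataset_fingerprint <- function(samples) {
  sums <- vapply(samples, function(s) sum(s$cloud) + s$label, numeric(1))
  sprintf("n%d_%.6e", length(samples), sum(sums))
}

#' Ablation runner over the module variants
#'
#' Trains the `baseline`, `dlf_only` and `full` variants under identical
#' data, seeds and hyperparameters, so the reported differences are purely
#' structural (grouping branches, convolution type, SE presence).
#'
#' @param train_samples,test_samples prepared sample lists.
#' @param model_cfg a [model_config()]; its `variant` field is overridden.
#' @param train_cfg a [train_config()].
#' @param variants variants to run.
#' @param seeds one or more seeds; each variant is trained once per seed.
#' @param verbose print progress.
#' @return data.frame with columns variant, seed, oa, macc and the shared
#'   dataset fingerprint; per-run [metrics_report()]s in attribute
#'   `"reports"`.
#' @export
run_ablation <- function(train_samples, test_samples, model_cfg,
                         train_cfg = train_config(),
                         variants = c("baseline", "dlf_only", "full"),
                         seeds = train_cfg$seed, verbose = FALSE) {
  fp <- dataset_fingerprint(c(train_samples, test_samples))
  rows <- list(); reports <- list()
  for (v in variants) {
    cfgv <- model_cfg
    cfgv$variant <- v
    for (sd in seeds) {
      tc <- train_cfg
      tc$seed <- as.integer(sd)
      model <- build_model(cfgv, seed = sd)
      fit <- train_model(model, train_samples, val_samples = test_samples,
                         cfg = tc, verbose = verbose)
      rep <- evaluate_model(fit$model, test_samples)
      key <- sprintf("%s_seed%d", v, sd)
      reports[[key]] <- rep
      rows[[key]] <- data.frame(variant = v, seed = sd, oa = rep$oa,
                                macc = rep$macc, dataset = fp,
                                stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}

#' Neighborhood-size sensitivity sweep
#'
#' Trains one model per `k` in the grid with everything else fixed.
#' Grid entries whose candidate shell (2k) exceeds the training cloud size
#' are skipped with a warning.
#'
#' @inheritParams run_ablation
#' @param k_grid neighborhood sizes to sweep.
#' @return data.frame with columns k, oa, macc; per-k [metrics_report()]s in
#'   attribute `"reports"`.
#' @export
run_k_sensitivity <- function(train_samples, test_samples, model_cfg,
                              train_cfg = train_config(),
                              k_grid = c(16, 20, 24, 28), verbose = FALSE) {
  rows <- list(); reports <- list()
  for (k in k_grid) {
    if (2L * k > model_cfg$input_points) {
      warnf("k = %d skipped: candidate shell 2k exceeds the cloud size %d",
            k, model_cfg$input_points)
      next
    }
    cfgk <- model_cfg
    cfgk$k <- as.integer(k)
    model <- build_model(cfgk, seed = train_cfg$seed)
    fit <- train_model(model, train_samples, val_samples = test_samples,
                       cfg = train_cfg, verbose = verbose)
    rep <- evaluate_model(fit$model, test_samples)
    key <- sprintf("k%d", k)
    reports[[key]] <- rep
    rows[[key]] <- data.frame(k = k, oa = rep$oa, macc = rep$macc)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  out
}
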