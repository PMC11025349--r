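#' Training configuration
#'
#' The reference protocol: a 4:1 image-level train/test split, fivefold
#' cross-validation on the training side, 200 phase-1 epochs with the
#' focal+Dice loss, then Hausdorff-distance fine-tuning of the phase-1 best
#' checkpoint, Adam optimisation with cosine learning-rate decay within each
#' phase, and model selection by validation Dice. [desk_train_config()]
#' fixes the scaled-down study conditions used throughout this package's
#' examples and tests: 128 px tiles, width divisor 8, 20 + 5 epochs.
#'
#' @param k_folds folds for cross-validation (>= 2).
#' @param epochs_phase1,epochs_phase2 epochs per phase (>= 1; phase 2 may
#'   be 0 to skip fine-tuning).
#' @param batch_size tiles per optimisation step.
#' @param lr_phase1,lr_phase2 Adam learning rates per phase.
#' @param seed master seed for shuffling and augmentation.
#' @param loss a [loss_config()].
#' @param aug an [aug_config()]; applied to training folds only.
#' @param network a [network_config()].
#' @return a `train_config` list.
#' @export
train_config <- function(k_folds = 5, epochs_phase1 = 200,
                         epochs_phase2 = 20, batch_size = 4,
                         lr_phase1 = 1e-3, lr_phase2 = 1e-4, seed = 1L,
                         loss = loss_config(), aug = aug_config(),
                         network = network_config()) {
  stopifnot(k_folds >= 2, epochs_phase1 >= 1, epochs_phase2 >= 0,
            batch_size >= 1)
  structure(list(k_folds = as.integer(k_folds),
                 epochs_phase1 = as.integer(epochs_phase1),
                 epochs_phase2 = as.integer(epochs_phase2),
                 batch_size = as.integer(batch_size),
                 lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
                 seed = as.integer(seed), loss = loss, aug = aug,
                 network = network), class = "train_config")
}

#' @rdname train_config
#' @export
desk_train_config <- function(seed = 1L) {
  train_config(k_folds = 5, epochs_phase1 = 20, epochs_phase2 = 5,
               batch_size = 2, lr_phase1 = 2e-3, seed = seed,
               aug = no_aug_config(),
               network = network_config(input_size = 128,
                                        width_divisor = 8))
}

#' Split samples into train and test sets at the image level
#'
#' @param samples list of samples (any objects).
#' @param ratio train fraction (default 0.8, the 4:1 split).
#' @param seed integer seed; the split is deterministic per seed.
#' @return list(train, test) of disjoint sublists covering `samples`.
#' @export
split_train_test <- function(samples, ratio = 0.8, seed = 1L) {
  n <- length(samples)
  if (n < 5) stop("split_train_test: need at least 5 samples, got ", n)
  n_train <- round(ratio * n)
  with_seed(seed, {
    idx <- sample.int(n)
    list(train = samples[sort(idx[seq_len(n_train)])],
         test = samples[sort(idx[-seq_len(n_train)])])
  })
}

#' Cut phantoms or image/mask pairs into training tiles
#'
#' @param samples list of `phantom_sample` objects (or lists with `image`
#'   and `mask`).
#' @param tile_size tile side in px.
#' @param overlap_fraction tile overlap (default 0: disjoint tiles).
#' @return list with `images`, `masks` (lists of matrices) and `source`
#'   (integer index of the originating sample, for leakage checks).
#' @export
prepare_tiles <- function(samples, tile_size, overlap_fraction = 0) {
  cfg <- tiling_config(tile_size, overlap_fraction)
  images <- list(); masks <- list(); source <- integer(0)
  for (i in seq_along(samples)) {
    ti <- tile_image(samples[[i]]$image, cfg)
    tm <- tile_image(samples[[i]]$mask, cfg)
    images <- c(images, ti$tiles)
    masks <- c(masks, lapply(tm$tiles, function(m) (m > 0.5) * 1L))
    source <- c(source, rep(i, length(ti$tiles)))
  }
  list(images = images, masks = masks, source = source)
}

# tree-structured Adam over the gradient structure returned by backward
adam_init <- function(grads) {
  zero_like <- function(g) {
    if (is.list(g)) lapply(g, zero_like) else g * 0
  }
  list(m = zero_like(grads), v = zero_like(grads), t = 0L)
}

adam_apply <- function(blocks, grads, state, lr, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  corr <- sqrt(1 - beta2^t) / (1 - beta1^t)
  upd <- function(p, g, m, v) {
    for (nm in names(g)) {
      if (is.list(g[[nm]])) {
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      } else {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        p[[nm]] <- p[[nm]] - lr * corr * m[[nm]] / (sqrt(v[[nm]]) + eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  r <- upd(blocks, grads, state$m, state$v)
  list(blocks = r$p, state = list(m = r$m, v = r$v, t = t))
}

cosine_lr <- function(base, epoch, total) {
  base * 0.5 * (1 + cos(pi * (epoch - 1) / max(total, 1)))
}

tile_dice <- function(pred_mask, gt_mask) {
  tp <- sum(pred_mask * gt_mask)
  denom <- 2 * tp + sum(pred_mask * (1 - gt_mask)) +
    sum((1 - pred_mask) * gt_mask)
  if (denom == 0) return(1)  # both empty
  2 * tp / denom
}

val_dice <- function(model, images, masks, batch_size = 4L,
                     threshold = 0.5) {
  if (!length(images)) return(NA_real_)
  preds <- net_forward(model, images, batch_size)
  mean(vapply(seq_along(preds), function(i)
    tile_dice(binarize(preds[[i]], threshold), masks[[i]]), numeric(1)))
}

#' Train one segmentation model with the two-phase loss schedule
#'
#' Phase 1 optimises the focal+Dice combination; phase 2 fine-tunes the
#' phase-1 best checkpoint (by validation Dice) with the Hausdorff-distance
#' surrogate at a lower learning rate. Aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param tiles list from [prepare_tiles()] (training tiles).
#' @param config a [train_config()]; `config$network$input_size` must match
#'   the tile size. If `config$aug` enables any op, a fresh augmented view
#'   of each tile is drawn every epoch (the validation tiles are never
#'   augmented).
#' @param val_tiles optional validation tiles (same structure); if missing,
#'   checkpoint selection falls back to training loss.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best checkpoint), `losses` (per-epoch mean
#'   training loss, both phases), `val_dice` (per-epoch validation Dice),
#'   `best_epoch`, and `phase1_model` (best checkpoint before fine-tuning).
#' @export
train_segmenter <- function(tiles, config, val_tiles = NULL,
                            verbose = FALSE) {
  sz <- config$network$input_size
  stopifnot(all(vapply(tiles$images, function(t) all(dim(t) == sz),
                       logical(1))))
  model <- build_network(config$network, seed = config$seed)
  n <- length(tiles$images)
  bs <- min(config$batch_size, n)
  losses <- numeric(0)
  vds <- numeric(0)
  best <- list(dice = -Inf, model = NULL, epoch = 0L)
  state <- NULL
  do_aug <- any(vapply(config$aug, function(o) (o$prob %||% 0) > 0,
                       logical(1)))

  run_phase <- function(model, state, phase, epochs, lr0) {
    for (ep in seq_len(epochs)) {
      lr <- cosine_lr(lr0, ep, epochs)
      ord <- with_seed(config$seed + 1000L * phase + ep, sample.int(n))
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = bs)) {
        ids <- ord[start:min(n, start + bs - 1)]
        B <- length(ids)
        imgs <- tiles$images[ids]
        msks <- tiles$masks[ids]
        if (do_aug) {
          for (k in seq_len(B)) {
            a <- augment(imgs[[k]], msks[[k]], config$aug,
                         seed = (config$seed + 7919L * ep +
                                   131L * ids[k]) %% 2147483647L)
            imgs[[k]] <- a$image
            msks[[k]] <- a$mask
          }
        }
        x <- array(unlist(imgs), dim = c(sz, sz, 1, B))
        t <- array(unlist(msks), dim = c(sz, sz, 1, B))
        fw <- net_forward_full(model, x, training = TRUE)
        model <- fw$model
        lg <- if (phase == 1) phase1_loss(fw$y, t, config$loss, grad = TRUE)
              else hd_loss_batch(fw$y, t, config$loss$hd_alpha)
        if (!is.finite(lg$loss))
          stop("train_segmenter: non-finite loss at phase ", phase,
               " epoch ", ep, "; aborting")
        grads <- net_backward_full(model, fw$caches, lg$grad)
        if (is.null(state)) state <- adam_init(grads)
        st <- adam_apply(model$blocks, grads, state, lr)
        model$blocks <- st$blocks
        state <- st$state
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1
      }
      losses <<- c(losses, ep_loss / nb)
      vd <- if (!is.null(val_tiles))
        val_dice(model, val_tiles$images, val_tiles$masks, bs) else
        -tail(losses, 1)
      vds <<- c(vds, if (!is.null(val_tiles)) vd else NA_real_)
      if (vd >= best$dice) {
        best <<- list(dice = vd, model = model, epoch = length(losses))
      }
      if (verbose)
        message(sprintf("phase %d epoch %d: loss %.4f val_dice %s",
                        phase, ep, tail(losses, 1),
                        ifelse(is.null(val_tiles), "-",
                               sprintf("%.3f", vd))))
    }
    list(model = model, state = state)
  }

  r1 <- run_phase(model, state, 1L, config$epochs_phase1, config$lr_phase1)
  phase1_model <- best$model
  phase1_model$meta$phase <- "phase1"
  if (config$epochs_phase2 > 0) {
    # fine-tune from the phase-1 best checkpoint with a fresh optimiser
    run_phase(phase1_model, NULL, 2L, config$epochs_phase2,
              config$lr_phase2)
  }
  out_model <- best$model
  out_model$meta$phase <- if (config$epochs_phase2 > 0 &&
                              best$epoch > config$epochs_phase1)
    "hd_finetuned" else "phase1"
  out_model$meta$epochs <- length(losses)
  list(model = out_model, losses = losses, val_dice = vds,
       best_epoch = best$epoch, phase1_model = phase1_model)
}

#' K-fold cross-validated training
#'
#' Splits the training samples into `k_folds` folds at the image level (no
#' tile of an image ever appears in both a training fold and its validation
#' fold), trains one model per fold with [train_segmenter()], applying the
#' configured augmentation to training-fold tiles only, and selects each
#' fold's best checkpoint by validation Dice.
#'
#' @param train_samples list of `phantom_sample`-like objects.
#' @param config a [train_config()].
#' @param verbose print progress.
#' @return list of fold results (see [train_segmenter()]), each with an
#'   added `fold` index and `val_indices`.
#' @export
train_folds <- function(train_samples, config, verbose = FALSE) {
  k <- config$k_folds
  n <- length(train_samples)
  if (n < k) stop("train_folds: fewer samples than folds")
  fold_id <- with_seed(config$seed, sample(rep_len(seq_len(k), n)))
  sz <- config$network$input_size
  lapply(seq_len(k), function(f) {
    tr <- which(fold_id != f)
    va <- which(fold_id == f)
    tr_tiles <- prepare_tiles(train_samples[tr], sz)
    va_tiles <- prepare_tiles(train_samples[va], sz)
    tr_tiles <- augment_tiles(tr_tiles, config$aug,
                              seed = config$seed + 131L * f)
    res <- train_segmenter(tr_tiles, config, va_tiles, verbose = verbose)
    res$fold <- f
    res$val_indices <- va
    res
  })
}

# dataset-level augmentation: cross-tile copy-paste (the per-tile geometric
# and photometric ops are drawn per epoch inside train_segmenter)
augment_tiles <- function(tiles, aug, seed = 1L) {
  n <- length(tiles$images)
  cp_prob <- aug$copy_paste$prob %||% 0
  with_seed(seed, {
    seeds <- sample.int(1e7, n)
    cp_fire <- runif(n) < cp_prob
    cp_ratio <- runif(n, min(aug$copy_paste$ratio %||% 0),
                      max(aug$copy_paste$ratio %||% 0))
    donors <- sample.int(n, n, replace = TRUE)
  })
  for (i in which(cp_fire)) {
    d <- donors[i]
    if (d == i) next
    r <- copy_paste(list(image = tiles$images[[d]],
                         mask = tiles$masks[[d]]),
                    list(image = tiles$images[[i]],
                         mask = tiles$masks[[i]]),
                    ratio = cp_ratio[i], seed = seeds[i] + 1L)
    tiles$images[[i]] <- r$image
    tiles$masks[[i]] <- r$mask
  }
  tiles
}

#' Segment a full mammogram with an ensemble of trained models
#'
#' Tiles the image, averages per-tile probabilities across models, stitches
#' the averaged tiles and thresholds the result.
#'
#' @param models list of `seg_model`s (>= 1), e.g. the per-fold best
#'   checkpoints.
#' @param image intensity matrix in \[0,1\].
#' @param tiling a [tiling_config()]; tile size must equal the models'
#'   input size.
#' @param threshold binarization threshold.
#' @return list with `mask` (binary matrix) and `probs` (stitched map).
#' @export
ensemble_predict <- function(models, image, tiling = NULL, threshold = 0.5) {
  if (!length(models)) stop("ensemble_predict: empty model list")
  sz <- models[[1]]$config$input_size
  tiling <- tiling %||% tiling_config(tile_size = sz)
  if (tiling$tile_size != sz)
    stop("ensemble_predict: tiling tile_size must match model input size")
  ts <- tile_image(image, tiling)
  acc <- NULL
  for (m in models) {
    p <- net_forward(m, ts$tiles)
    acc <- if (is.null(acc)) p else Map(`+`, acc, p)
  }
  mean_tiles <- lapply(acc, function(a) a / length(models))
  probs <- stitch(ts, mean_tiles)
  list(mask = binarize(probs, threshold), probs = probs)
}
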