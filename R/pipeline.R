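# End-to-end orchestration: supervised training with the rim-constrained
# loss (optionally from a self-supervised checkpoint), evaluation over a
# labeled set, and single-image prediction with PNG output.

#' Supervised training configuration
#'
#' Defaults follow the full supervised recipe: 100 epochs, Adam at 1e-4
#' decayed by 10x every 50 epochs, batch size 1 (GroupNorm in the encoder
#' avoids degenerate batch statistics at this batch size).
#'
#' @param epochs,lr,lr_decay,decay_every,batch schedule values (all
#'   positive).
#' @param seed master seed: shuffling, validation split and weight
#'   initialization all derive from it.
#' @param clip_norm global gradient-norm clip (default 1.0; `NULL` disables).
#'   The rim term's logarithmic gradient spikes while the disc-cup margin
#'   sits near the clamp boundary early in training; clipping keeps those
#'   steps bounded.
#' @param eps clamp constant of the rim loss.
#' @param val_frac fraction of the training samples held out for checkpoint
#'   selection when no explicit validation set is given.
#' @return a list of class `train_config`.
#' @export
trainConfig <- function(epochs = 100L, lr = 1e-4, lr_decay = 0.1,
                        decay_every = 50L, batch = 1L, seed = 1L,
                        clip_norm = 1.0, eps = 1e-6, val_frac = 0.2) {
  stopifnot(epochs >= 1, lr > 0, lr_decay > 0, decay_every >= 1, batch >= 1,
            eps > 0, val_frac >= 0, val_frac < 1,
            is.null(clip_norm) || clip_norm > 0)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 batch = as.integer(batch), seed = as.integer(seed),
                 clip_norm = clip_norm, eps = eps, val_frac = val_frac),
            class = "train_config")
}

sample_loss_node <- function(model, sample, eps) {
  out <- forward_segnet(model, sample)
  pd <- nd_sigmoid(nd_rows(out$logits, 1L))
  pc <- nd_sigmoid(nd_rows(out$logits, 2L))
  gd <- matrix(as.vector(t(discMask(sample))), 1L)
  gcup <- matrix(as.vector(t(cupMask(sample))), 1L)
  fw_rim_loss(pd, pc, gd, gcup, eps = eps)
}

val_metrics <- function(model, val_samples, eps) {
  losses <- numeric(length(val_samples))
  f1d <- numeric(length(val_samples))
  f1c <- numeric(length(val_samples))
  for (i in seq_along(val_samples)) {
    s <- val_samples[[i]]
    pred <- predictMasks(model, s)
    losses[i] <- as.numeric(rimLoss(pred$prob, discMask(s), cupMask(s),
                                    eps = eps))
    f1d[i] <- f1Score(confusionCounts(pred$disc, discMask(s)))
    f1c[i] <- f1Score(confusionCounts(pred$cup, cupMask(s)))
  }
  c(loss = mean(losses), f1_disc = mean(f1d), f1_cup = mean(f1c))
}

#' Train the segmentation network
#'
#' Optimizes the rim-constrained multi-label loss with Adam under the
#' configured schedule. Per-epoch training loss, validation loss and
#' validation F1 are logged; the checkpoint with the best validation mean F1
#' is kept. Fully deterministic for a given seed.
#'
#' @param samples list of labeled [FundusImage-class] objects or a manifest
#'   path.
#' @param config a [trainConfig()].
#' @param model optional pre-built [segNet()]; otherwise constructed from
#'   `model_config` (seeded by the training seed).
#' @param model_config configuration used when `model` is `NULL`.
#' @param init optional self-supervised checkpoint (path or model) whose
#'   encoder weights initialize the network.
#' @param steps optional cap on the total number of optimizer steps (for
#'   scaled-down runs); the schedule still follows epochs.
#' @param val_samples optional explicit validation set; by default
#'   `val_frac` of `samples` is split off by seed.
#' @param log_path optional CSV path for the epoch log.
#' @param checkpoint_path optional path for the best-validation checkpoint.
#' @return list with `model` (best validation weights), `log` (data.frame),
#'   `best_epoch`.
#' @export
trainModel <- function(samples, config = trainConfig(), model = NULL,
                       model_config = NULL, init = NULL, steps = NULL,
                       val_samples = NULL, log_path = NULL,
                       checkpoint_path = NULL) {
  if (is.character(samples)) samples <- loadManifest(samples)
  if (length(samples) == 0L) stop("no training samples")
  if (!all(vapply(samples, isLabeled, logical(1))))
    stop("manifest contains unlabeled images; training needs masks")
  if (is.null(model)) {
    if (is.null(model_config))
      model_config <- segNetConfig("shallow", seed = config$seed)
    model <- segNet(model_config)
  }
  if (!is.null(init)) transferWeights(init, model)
  if (is.null(val_samples) && config$val_frac > 0 && length(samples) >= 5L) {
    n_val <- max(1L, round(config$val_frac * length(samples)))
    idx <- with_seed(config$seed + 7L, sample(length(samples), n_val))
    val_samples <- samples[idx]
    samples <- samples[-idx]
  }
  opt <- adam_new(model$params, lr = config$lr)
  log <- list()
  best <- list(score = -Inf, params = NULL, epoch = NA_integer_)
  gstep <- 0L
  done <- FALSE
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      if (done) break
      lr_ep <- config$lr * config$lr_decay^((ep - 1L) %/% config$decay_every)
      ord <- sample(length(samples))
      ep_losses <- c()
      for (start in seq(1L, length(ord), by = config$batch)) {
        ids <- ord[start:min(start + config$batch - 1L, length(ord))]
        loss <- NULL
        for (id in ids) {
          l1 <- sample_loss_node(model, samples[[id]], config$eps)
          loss <- if (is.null(loss)) l1 else nd_add(loss, l1)
        }
        if (length(ids) > 1L) loss <- nd_scale(loss, 1 / length(ids))
        nd_backward(loss)
        adam_step(opt, lr = lr_ep, clip_norm = config$clip_norm)
        ep_losses <- c(ep_losses, nd_value(loss))
        gstep <- gstep + 1L
        if (!is.null(steps) && gstep >= steps) { done <- TRUE; break }
      }
      row <- data.frame(epoch = ep, steps = gstep,
                        train_loss = mean(ep_losses),
                        val_loss = NA_real_, val_f1_disc = NA_real_,
                        val_f1_cup = NA_real_)
      if (!is.null(val_samples)) {
        vm <- val_metrics(model, val_samples, config$eps)
        row$val_loss <- vm[["loss"]]
        row$val_f1_disc <- vm[["f1_disc"]]
        row$val_f1_cup <- vm[["f1_cup"]]
        score <- (vm[["f1_disc"]] + vm[["f1_cup"]]) / 2
        if (score > best$score) {
          best$score <- score
          best$epoch <- ep
          best$params <- lapply(model$params, function(p) p$value)
        }
      }
      log[[ep]] <- row
    }
  })
  if (!is.null(best$params))
    for (nm in names(best$params)) model$params[[nm]]$value <- best$params[[nm]]
  log <- do.call(rbind, log)
  if (!is.null(log_path)) write.csv(log, log_path, row.names = FALSE)
  if (!is.null(checkpoint_path)) saveCheckpoint(model, checkpoint_path)
  list(model = model, log = log, best_epoch = best$epoch)
}

#' Evaluate a checkpoint over a labeled set
#'
#' Runs [predictMasks()] on every image, computes the full metric set per
#' image ([evaluateMasks()]) and appends a mean row.
#'
#' @param model a `segnet` model or checkpoint path.
#' @param samples labeled samples (list or manifest path).
#' @param out_csv optional CSV output path.
#' @param clip_cup passed to [predictMasks()].
#' @return a data.frame with one row per image plus a final `mean` row.
#' @export
evaluateModel <- function(model, samples, out_csv = NULL, clip_cup = FALSE) {
  if (is.character(model)) model <- loadCheckpoint(model)
  if (is.character(samples)) samples <- loadManifest(samples)
  if (!all(vapply(samples, isLabeled, logical(1))))
    stop("evaluation requires ground-truth masks")
  rows <- lapply(samples, function(s) {
    pred <- predictMasks(model, s, clip_cup = clip_cup)
    cbind(data.frame(id = sampleId(s)),
          evaluateMasks(pred$disc, pred$cup, discMask(s), cupMask(s)))
  })
  df <- do.call(rbind, rows)
  mean_row <- df[1, , drop = FALSE]
  mean_row$id <- "mean"
  for (cl in setdiff(names(df), "id"))
    mean_row[[cl]] <- mean(df[[cl]], na.rm = TRUE)
  df <- rbind(df, mean_row)
  rownames(df) <- NULL
  if (!is.null(out_csv)) write.csv(df, out_csv, row.names = FALSE)
  df
}

#' Predict masks for an image file
#'
#' Reads an RGB PNG, resizes to the nearest multiple of 32 if necessary,
#' predicts, resizes the probability maps back with the recorded inverse
#' transform, thresholds, and writes the three-level mask PNG
#' (0 background / 128 disc-only / 255 cup). Deterministic and idempotent.
#'
#' @param model a `segnet` model or checkpoint path.
#' @param image_path input PNG path.
#' @param out_path output mask PNG path.
#' @param threshold probability threshold.
#' @param clip_cup force cup inside disc in the written mask.
#' @return `out_path`, invisibly.
#' @export
predictToFile <- function(model, image_path, out_path,
                          threshold = NULL, clip_cup = FALSE) {
  if (is.character(model)) model <- loadCheckpoint(model)
  if (is.null(threshold)) threshold <- model$config$threshold
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  H <- dim(img)[1]; W <- dim(img)[2]
  H32 <- max(32L, as.integer(round(H / 32)) * 32L)
  W32 <- max(32L, as.integer(round(W / 32)) * 32L)
  work <- if (H == H32 && W == W32) img else resizeImage(img, H32, W32)
  mp <- decodeImage(model, clip01(work))
  pd <- discProb(mp); pc <- cupProb(mp)
  if (H != H32 || W != W32) {
    pd <- resizeImage(pd, H, W)
    pc <- resizeImage(pc, H, W)
  }
  disc <- largest_component((pd > threshold) + 0)
  cup <- largest_component((pc > threshold) + 0)
  if (clip_cup) cup <- cup * disc
  write_mask_png(disc, cup, out_path)
  invisible(out_path)
}
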