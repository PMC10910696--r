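# Contrastive self-supervised pretraining of the encoder: two augmented
# views per image share the encoder, the deepest feature map is pooled by a
# full-image RoiAlign to a fixed 24x24 grid, flattened, projected by a fully
# connected head, L2-normalized, and trained with the in-batch InfoNCE
# objective.

#' Augmentation configuration for pretraining
#'
#' The four augmentations and their parameter ranges: quarter-turn rotation
#' (0/90/180/270 degrees), kernel sharpening alpha-blended with the original
#' (`alpha` in `[0, 1]`), gamma contrast (`gamma` in `[0.5, 2]`) and Gaussian
#' blur (`sigma` in `[0, 0.5]`).
#'
#' @param rotation_choices rotation angles in degrees.
#' @param sharpen_alpha_range,gamma_range,blur_sigma_range numeric ranges.
#' @return a list of class `AugmentationConfig`.
#' @export
augmentConfig <- function(rotation_choices = c(0, 90, 180, 270),
                          sharpen_alpha_range = c(0, 1),
                          gamma_range = c(0.5, 2.0),
                          blur_sigma_range = c(0, 0.5)) {
  structure(list(rotation_choices = rotation_choices,
                 sharpen_alpha_range = sharpen_alpha_range,
                 gamma_range = gamma_range,
                 blur_sigma_range = blur_sigma_range),
            class = "AugmentationConfig")
}

#' Sample and apply one augmented view
#'
#' Applies, in order: one uniformly chosen rotation, sharpening alpha-blended
#' with the input, gamma contrast, and Gaussian blur, with parameters drawn
#' uniformly from the configured ranges. The output is clipped to `[0, 1]`.
#' Deterministic for a given `seed` (or the current RNG state when `seed` is
#' `NULL`).
#'
#' @param image H x W x 3 array in `[0, 1]` (or a [FundusImage-class]).
#' @param config an [augmentConfig()].
#' @param seed optional integer seed.
#' @return the augmented image array, with the sampled parameters attached
#'   as attribute `"draws"`.
#' @export
augmentView <- function(image, config = augmentConfig(), seed = NULL) {
  if (is(image, "FundusImage")) image <- imagePixels(image)
  with_seed(seed, {
    rot_deg <- sample(config$rotation_choices, 1L)
    alpha <- runif(1, config$sharpen_alpha_range[1], config$sharpen_alpha_range[2])
    gam <- runif(1, config$gamma_range[1], config$gamma_range[2])
    sig <- runif(1, config$blur_sigma_range[1], config$blur_sigma_range[2])
    out <- rotateImage(image, rot_deg / 90)
    out <- clip01((1 - alpha) * out + alpha * sharpenImage(out))
    out <- clip01(out^gam)
    out <- clip01(blurImage(out, sig))
    attr(out, "draws") <- c(rotation = rot_deg, alpha = alpha,
                            gamma = gam, sigma = sig)
    out
  })
}

## ---- projection head ------------------------------------------------------

init_ssl_head <- function(model, embed_dim = 128L, pooled = 24L) {
  if (!is.null(model$params[["ssl.head.w"]])) return(invisible(model))
  C4 <- model$config$widths[4]
  fan_in <- C4 * pooled * pooled
  with_seed(model$config$seed + 1L, {
    reg_param(model, "ssl.head.w",
              matrix(rnorm(embed_dim * fan_in, 0, sqrt(1 / fan_in)),
                     embed_dim, fan_in))
    reg_param(model, "ssl.head.b", rep(0, embed_dim))
  })
  model$ssl_pooled <- as.integer(pooled)
  invisible(model)
}

# node-level: image array -> unit-norm embedding column
fw_embed <- function(model, image, pooled = 24L) {
  d <- dim(image)
  check_divisible(d[1], d[2])
  enc <- fw_encoder(model, nd_const(image_to_cmat(image)), d[1], d[2])
  f4 <- enc$feats[[4]]
  pool <- nd_roialign(f4$x, f4$h, f4$w, out = pooled, sampling = 2L)
  vec <- nd_reshape(pool, c(length(nd_value(pool)), 1L))
  emb <- nd_add(nd_mm(get_p(model, "ssl.head.w"), vec),
                get_p(model, "ssl.head.b"))
  nd_l2norm_cols(emb)
}

#' Contrastive embedding of an image
#'
#' Encodes the image, pools the deepest feature map with a full-image-box
#' RoiAlign to a 24 x 24 grid (so the embedding dimension is independent of
#' the input resolution), flattens, applies the fully connected projection
#' and L2-normalizes.
#'
#' @param model a [segNet()] model (the projection head is created on first
#'   use).
#' @param image a [FundusImage-class] or H x W x 3 array.
#' @param embed_dim projection dimension (default 128).
#' @return a unit-norm numeric vector of length `embed_dim`.
#' @export
contrastiveEmbed <- function(model, image, embed_dim = 128L) {
  if (is(image, "FundusImage")) image <- imagePixels(image)
  init_ssl_head(model, embed_dim = embed_dim)
  as.vector(nd_value(fw_embed(model, image)))
}

## ---- pretraining loop -----------------------------------------------------

#' Self-supervised contrastive pretraining
#'
#' For each mini-batch of unlabeled images, builds two independently
#' augmented views per image, embeds all views with the shared (siamese)
#' encoder and projection head, computes the in-batch InfoNCE loss (for
#' batch size B every anchor sees its partner as the positive and the other
#' `2(B-1)` views as negatives) and updates encoder and head with Adam.
#' Defaults follow the pretraining recipe: 30 epochs, learning rate 1e-4
#' decayed by 10x every 15 epochs, batch size 8, temperature 0.07.
#'
#' @param samples list of [FundusImage-class] (masks not required) or a
#'   manifest path.
#' @param model optional existing [segNet()] model; a fresh one is built
#'   from `model_config` otherwise.
#' @param model_config configuration for a fresh model.
#' @param epochs,lr,lr_decay,decay_every,batch,tau training schedule.
#' @param embed_dim projection dimension.
#' @param seed seed controlling shuffling and augmentation draws.
#' @param log_path optional CSV path for the per-step loss log.
#' @param checkpoint_path optional path for the resulting checkpoint (the
#'   projection head is stored alongside the encoder weights).
#' @return a list with `model`, `log` (data.frame epoch/step/loss) and
#'   `final_loss`.
#' @export
pretrainEncoder <- function(samples, model = NULL,
                            model_config = segNetConfig(),
                            epochs = 30L, lr = 1e-4, lr_decay = 0.1,
                            decay_every = 15L, batch = 8L, tau = 0.07,
                            embed_dim = 128L, seed = 1L,
                            log_path = NULL, checkpoint_path = NULL) {
  if (is.character(samples)) samples <- loadManifest(samples)
  if (length(samples) == 0L) stop("empty manifest: nothing to pretrain on")
  if (length(samples) < batch)
    stop("need at least ", batch, " images for batch size ", batch)
  if (is.null(model)) model <- segNet(model_config)
  init_ssl_head(model, embed_dim = embed_dim)
  opt <- adam_new(model$params, lr = lr)
  aug <- augmentConfig()
  log <- list()
  gstep <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      lr_ep <- lr * lr_decay^((ep - 1L) %/% decay_every)
      ord <- sample(length(samples))
      nb <- length(ord) %/% batch
      for (bi in seq_len(nb)) {
        ids <- ord[((bi - 1L) * batch + 1L):(bi * batch)]
        embs <- vector("list", 2L * batch)
        for (j in seq_along(ids)) {
          img <- imagePixels(samples[[ids[j]]])
          embs[[2L * j - 1L]] <- fw_embed(model, augmentView(img, aug))
          embs[[2L * j]] <- fw_embed(model, augmentView(img, aug))
        }
        # column-bind the unit embeddings: d x 2B
        E <- nd_rbind(lapply(embs, nd_t))
        loss <- fw_info_nce_batch(nd_t(E), tau = tau)
        nd_backward(loss)
        adam_step(opt, lr = lr_ep)
        loss_val <- nd_value(loss)
        rm(embs, E, loss)
        gc(FALSE)   # 2B live forward tapes per batch; trim promptly
        gstep <- gstep + 1L
        log[[gstep]] <- data.frame(epoch = ep, step = gstep,
                                   loss = loss_val)
      }
    }
  })
  log <- do.call(rbind, log)
  if (!is.null(log_path))
    write.csv(log, log_path, row.names = FALSE)
  if (!is.null(checkpoint_path)) saveCheckpoint(model, checkpoint_path)
  list(model = model, log = log,
       final_loss = if (nrow(log)) log$loss[nrow(log)] else NA_real_)
}

#' Transfer pretrained encoder weights into a segmentation network
#'
#' Copies every encoder-side parameter (stem, residual stages, attention
#' blocks) from a pretraining checkpoint or model into `target`; decoder and
#' head parameters keep their fresh initialization. Mismatched encoder
#' shapes raise an error listing the offending layers.
#'
#' @param source a checkpoint path or a pretrained `segnet` model.
#' @param target the segmentation model to initialize.
#' @return `target` (modified in place), with a transfer report attached as
#'   attribute `"report"`: `transferred` and `skipped` parameter names.
#' @export
transferWeights <- function(source, target) {
  if (is.character(source)) source <- loadCheckpoint(source)
  src <- lapply(source$params, function(p) p$value)
  enc_names <- grep("^enc\\.", names(src), value = TRUE)
  bad <- character()
  for (nm in enc_names) {
    tp <- target$params[[nm]]
    if (is.null(tp) ||
        !identical(dim_or_len(tp$value), dim_or_len(src[[nm]])))
      bad <- c(bad, nm)
  }
  if (length(bad) > 0L)
    stop("incompatible encoder configuration; offending layers: ",
         paste(bad, collapse = ", "))
  for (nm in enc_names) target$params[[nm]]$value <- src[[nm]]
  skipped <- setdiff(names(target$params), enc_names)
  attr(target, "report") <- list(transferred = enc_names, skipped = skipped)
  invisible(target)
}
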