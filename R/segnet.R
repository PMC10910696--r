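# The attention-aware pyramid encoder-decoder. A residual CNN encoder
# produces feature maps at strides 4/8/16/32; a multi-scale attention block
# follows every stage and the aggregation attention block follows stage 4;
# a skip-connected bilinear-upsampling decoder restores full resolution and
# a 1x1 head emits independent disc and cup logits (multi-label).

#' Segmentation network configuration
#'
#' @param preset encoder preset: `"shallow"` (stage widths 12/24/48/96, one
#'   residual block per stage; intended for CPU-scale experiments and tests),
#'   `"standard"` (64/128/256/512, two blocks) or `"resnet34"`
#'   (64/128/256/512 with 3/4/6/3 blocks, mirroring the 34-layer residual
#'   layout).
#' @param widths optional explicit stage channel widths (length 4).
#' @param blocks optional residual blocks per stage (length 4).
#' @param heads attention heads in the multi-scale attention blocks
#'   (default 4; widths must be divisible).
#' @param scales KNN neighbor scales (default `c(4, 6, 8)`), clipped to the
#'   token count at the coarsest stages.
#' @param clusters clusters of the aggregation attention block (default 3:
#'   disc, cup, background token populations).
#' @param norm `"group"` (GroupNorm, default: supervised training uses batch
#'   size 1, where batch statistics degenerate) or `"instance"` (per-channel
#'   statistics, the batch-norm-at-batch-1 behaviour).
#' @param groups GroupNorm group count (default 4).
#' @param threshold probability threshold for [predictMasks()].
#' @param seed seed for weight initialization and for the deterministic
#'   k-means assignment inside the aggregation block.
#' @return a list of class `segnet_config`.
#' @export
segNetConfig <- function(preset = c("shallow", "standard", "resnet34"),
                         widths = NULL, blocks = NULL, heads = 4L,
                         scales = c(4L, 6L, 8L), clusters = 3L,
                         norm = c("group", "instance"), groups = 4L,
                         threshold = 0.5, seed = 1L) {
  preset <- match.arg(preset)
  norm <- match.arg(norm)
  # the shallow preset keeps the per-head dimension at 6 (C = 12 at stage 1)
  if (preset == "shallow" && missing(heads)) heads <- 2L
  def <- switch(preset,
    shallow  = list(widths = c(12L, 24L, 48L, 96L), blocks = rep(1L, 4)),
    standard = list(widths = c(64L, 128L, 256L, 512L), blocks = rep(2L, 4)),
    resnet34 = list(widths = c(64L, 128L, 256L, 512L),
                    blocks = c(3L, 4L, 6L, 3L)))
  widths <- as.integer(if (is.null(widths)) def$widths else widths)
  blocks <- as.integer(if (is.null(blocks)) def$blocks else blocks)
  stopifnot(length(widths) == 4L, length(blocks) == 4L)
  if (any(widths %% heads != 0L))
    stop("all stage widths must be divisible by the head count")
  structure(list(preset = preset, widths = widths, blocks = blocks,
                 heads = as.integer(heads), scales = as.integer(scales),
                 clusters = as.integer(clusters), norm = norm,
                 groups = as.integer(groups), threshold = threshold,
                 seed = as.integer(seed)),
            class = "segnet_config")
}

norm_groups <- function(config, C) {
  if (config$norm == "instance") C else min(config$groups, C)
}

## ---- parameter registry ---------------------------------------------------

reg_param <- function(model, name, value) {
  model$params[[name]] <- nd_param(value)
  model$params[[name]]
}

# register every numeric leaf of a nested list under dotted names; returns
# the same structure with leaves replaced by parameter nodes
register_tree <- function(model, prefix, tree) {
  out <- tree
  for (nm in names(tree)) {
    leaf <- tree[[nm]]
    if (is.list(leaf)) {
      out[[nm]] <- register_tree(model, paste0(prefix, ".", nm), leaf)
    } else if (is.numeric(leaf) && nm %in% c("heads", "scales")) {
      out[[nm]] <- leaf
    } else if (is.numeric(leaf)) {
      out[[nm]] <- reg_param(model, paste0(prefix, ".", nm), leaf)
    }
  }
  out
}

conv_w <- function(Cout, Cin, k) {
  matrix(rnorm(Cout * Cin * k * k, 0, sqrt(2 / (Cin * k * k))),
         Cout, Cin * k * k)
}

add_conv <- function(model, name, Cin, Cout, k) {
  reg_param(model, paste0(name, ".w"), conv_w(Cout, Cin, k))
  reg_param(model, paste0(name, ".b"), rep(0, Cout))
}
add_norm <- function(model, name, C) {
  reg_param(model, paste0(name, ".g"), rep(1, C))
  reg_param(model, paste0(name, ".b"), rep(0, C))
}
add_block <- function(model, name, Cin, Cout, stride) {
  add_conv(model, paste0(name, ".conv1"), Cin, Cout, 3L)
  add_norm(model, paste0(name, ".n1"), Cout)
  add_conv(model, paste0(name, ".conv2"), Cout, Cout, 3L)
  add_norm(model, paste0(name, ".n2"), Cout)
  if (stride > 1L || Cin != Cout) {
    add_conv(model, paste0(name, ".proj"), Cin, Cout, 1L)
    add_norm(model, paste0(name, ".nproj"), Cout)
  }
}

#' Build an attention-aware segmentation network
#'
#' Initializes all parameters (He initialization for convolutions; the
#' residual branches of the attention blocks start at zero so every block is
#' initially an identity) under the configuration seed.
#'
#' @param config a [segNetConfig()] object.
#' @return a model environment of class `segnet` holding the parameter nodes
#'   and the configuration.
#' @export
segNet <- function(config = segNetConfig()) {
  model <- new.env(parent = emptyenv())
  model$params <- list()
  model$config <- config
  w <- config$widths
  with_seed(config$seed, {
    add_conv(model, "enc.stem1", 3L, w[1], 3L)
    add_norm(model, "enc.stem1.n", w[1])
    add_conv(model, "enc.stem2", w[1], w[1], 3L)
    add_norm(model, "enc.stem2.n", w[1])
    cin <- w[1]
    for (i in 1:4) {
      for (b in seq_len(config$blocks[i])) {
        stride <- if (i > 1L && b == 1L) 2L else 1L
        add_block(model, sprintf("enc.s%d.b%d", i, b),
                  if (b == 1L) cin else w[i], w[i], stride)
      }
      cin <- w[i]
      model[[sprintf("msa%d", i)]] <- register_tree(
        model, sprintf("enc.msa%d", i),
        attentionParams(w[i], heads = config$heads, scales = config$scales))
    }
    model$agg <- register_tree(model, "enc.agg", aggregationParams(w[4]))
    # decoder: three skip fusions, one stem skip, one plain stage, 1x1 head
    dec_in <- c(w[4] + w[3], w[3] + w[2], w[2] + w[1], w[1] + w[1], w[1])
    dec_out <- c(w[3], w[2], w[1], w[1], w[1])
    for (i in seq_along(dec_in)) {
      add_conv(model, sprintf("dec.d%d.conv1", i), dec_in[i], dec_out[i], 3L)
      add_norm(model, sprintf("dec.d%d.n1", i), dec_out[i])
      add_conv(model, sprintf("dec.d%d.conv2", i), dec_out[i], dec_out[i], 3L)
      add_norm(model, sprintf("dec.d%d.n2", i), dec_out[i])
    }
    add_conv(model, "dec.head", w[1], 2L, 1L)
    # sparse-foreground prior: disc/cup cover a minority of pixels, so start
    # the output logits at log(0.1/0.9) instead of 0
    model$params[["dec.head.b"]]$value <- rep(log(0.1 / 0.9), 2L)
  })
  class(model) <- c("segnet", "environment")
  model
}

#' @export
print.segnet <- function(x, ...) {
  cat(sprintf("segnet (%s preset): widths %s, heads %d, %d parameters\n",
              x$config$preset, paste(x$config$widths, collapse = "/"),
              x$config$heads, countParams(x)))
  invisible(x)
}

#' Total number of learnable parameters
#' @param model a `segnet` model.
#' @export
countParams <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

get_p <- function(model, name) {
  p <- model$params[[name]]
  if (is.null(p)) stop("unknown parameter: ", name)
  p
}

## ---- forward passes -------------------------------------------------------

fw_conv_norm_relu <- function(model, name, fm, stride = 1L, config) {
  y <- nd_conv2d(fm$x, get_p(model, paste0(name, ".w")),
                 get_p(model, paste0(name, ".b")), fm$h, fm$w,
                 stride = stride)
  h <- attr(y, "ho"); w2 <- attr(y, "wo")
  C <- length(get_p(model, paste0(name, ".b"))$value)
  y <- nd_groupnorm(y, get_p(model, paste0(name, ".n.g")),
                    get_p(model, paste0(name, ".n.b")),
                    groups = norm_groups(config, C))
  list(x = nd_relu(y), h = h, w = w2)
}

fw_res_block <- function(model, name, fm, stride, config) {
  has_proj <- !is.null(model$params[[paste0(name, ".proj.w")]])
  C <- length(get_p(model, paste0(name, ".conv1.b"))$value)
  g <- norm_groups(config, C)
  y <- nd_conv2d(fm$x, get_p(model, paste0(name, ".conv1.w")),
                 get_p(model, paste0(name, ".conv1.b")), fm$h, fm$w,
                 stride = stride)
  h <- attr(y, "ho"); w2 <- attr(y, "wo")
  y <- nd_relu(nd_groupnorm(y, get_p(model, paste0(name, ".n1.g")),
                            get_p(model, paste0(name, ".n1.b")), groups = g))
  y <- nd_conv2d(y, get_p(model, paste0(name, ".conv2.w")),
                 get_p(model, paste0(name, ".conv2.b")), h, w2, stride = 1L)
  y <- nd_groupnorm(y, get_p(model, paste0(name, ".n2.g")),
                    get_p(model, paste0(name, ".n2.b")), groups = g)
  skip <- if (has_proj) {
    s <- nd_conv2d(fm$x, get_p(model, paste0(name, ".proj.w")),
                   get_p(model, paste0(name, ".proj.b")), fm$h, fm$w,
                   stride = stride)
    nd_groupnorm(s, get_p(model, paste0(name, ".nproj.g")),
                 get_p(model, paste0(name, ".nproj.b")), groups = g)
  } else fm$x
  list(x = nd_relu(nd_add(y, skip)), h = h, w = w2)
}

# encoder: image (C x H*W node) -> list of pyramid features; every stage is
# followed by its multi-scale attention block, stage 4 additionally by the
# aggregation attention block
fw_encoder <- function(model, x, h, w) {
  config <- model$config
  fm <- list(x = x, h = h, w = w)
  s2 <- fw_conv_norm_relu(model, "enc.stem1", fm, stride = 2L, config)
  fm <- fw_conv_norm_relu(model, "enc.stem2", s2, stride = 2L, config)
  feats <- vector("list", 4L)
  for (i in 1:4) {
    for (b in seq_len(config$blocks[i])) {
      stride <- if (i > 1L && b == 1L) 2L else 1L
      fm <- fw_res_block(model, sprintf("enc.s%d.b%d", i, b), fm, stride,
                         config)
    }
    fm$x <- fw_ms_attention(fm$x, model[[sprintf("msa%d", i)]],
                            clip_scales = TRUE)
    if (i == 4L)
      fm$x <- fw_aggregation(fm$x, model$agg, clusters = config$clusters,
                             seed = config$seed)
    feats[[i]] <- fm
  }
  list(feats = feats, stem = s2)
}

fw_dec_stage <- function(model, i, fm, skip, config) {
  up <- nd_upsample2x(fm$x, fm$h, fm$w)
  h <- attr(up, "ho"); w2 <- attr(up, "wo")
  x <- if (is.null(skip)) up else nd_rbind(list(up, skip$x))
  name <- sprintf("dec.d%d", i)
  C <- length(get_p(model, paste0(name, ".conv1.b"))$value)
  g <- norm_groups(config, C)
  y <- nd_conv2d(x, get_p(model, paste0(name, ".conv1.w")),
                 get_p(model, paste0(name, ".conv1.b")), h, w2)
  y <- nd_relu(nd_groupnorm(y, get_p(model, paste0(name, ".n1.g")),
                            get_p(model, paste0(name, ".n1.b")), groups = g))
  y <- nd_conv2d(y, get_p(model, paste0(name, ".conv2.w")),
                 get_p(model, paste0(name, ".conv2.b")), h, w2)
  y <- nd_relu(nd_groupnorm(y, get_p(model, paste0(name, ".n2.g")),
                            get_p(model, paste0(name, ".n2.b")), groups = g))
  list(x = y, h = h, w = w2)
}

fw_decoder <- function(model, enc) {
  config <- model$config
  feats <- enc$feats
  fm <- feats[[4]]
  fm <- fw_dec_stage(model, 1L, fm, feats[[3]], config)
  fm <- fw_dec_stage(model, 2L, fm, feats[[2]], config)
  fm <- fw_dec_stage(model, 3L, fm, feats[[1]], config)
  fm <- fw_dec_stage(model, 4L, fm, enc$stem, config)
  fm <- fw_dec_stage(model, 5L, fm, NULL, config)
  logits <- nd_conv2d(fm$x, get_p(model, "dec.head.w"),
                      get_p(model, "dec.head.b"), fm$h, fm$w)
  list(logits = logits, h = fm$h, w = fm$w)
}

check_divisible <- function(H, W) {
  if (H %% 32L != 0L || W %% 32L != 0L)
    stop("input size ", H, "x", W, " is not divisible by 32; ",
         "resize required before encoding")
}

# full forward: FundusImage or H x W x 3 array -> logits node + spatial size
forward_segnet <- function(model, image) {
  if (is(image, "FundusImage")) image <- imagePixels(image)
  d <- dim(image)
  check_divisible(d[1], d[2])
  x <- nd_const(image_to_cmat(image))
  enc <- fw_encoder(model, x, d[1], d[2])
  fw_decoder(model, enc)
}

#' Encode an image into pyramid features
#'
#' Runs the encoder half of the network: stem, four residual stages each
#' followed by a multi-scale attention block, and the aggregation attention
#' block after stage 4. Feature maps come back at strides 4, 8, 16 and 32.
#'
#' @param model a [segNet()] model.
#' @param image a [FundusImage-class] or H x W x 3 array; H and W must be
#'   divisible by 32.
#' @return a list of four `TokenTensor` objects (one per stage).
#' @export
encodeImage <- function(model, image) {
  if (is(image, "FundusImage")) image <- imagePixels(image)
  d <- dim(image)
  check_divisible(d[1], d[2])
  enc <- fw_encoder(model, nd_const(image_to_cmat(image)), d[1], d[2])
  lapply(enc$feats, function(fm) {
    new("TokenTensor", values = nd_value(fm$x),
        gridShape = c(fm$h, fm$w), groupSize = 1L)
  })
}

#' Decode an image into disc/cup probability maps
#'
#' Full forward pass: encoder, attention blocks, skip-connected decoder and
#' sigmoid multi-label head (an independent binary classifier per
#' structure).
#'
#' @inheritParams encodeImage
#' @return a [MaskPair-class] with probabilities and logits at the input
#'   resolution.
#' @export
decodeImage <- function(model, image) {
  out <- forward_segnet(model, image)
  lv <- nd_value(out$logits)
  pv <- 1 / (1 + exp(-lv))
  new("MaskPair",
      pDisc = matrix(pv[1, ], out$h, out$w, byrow = TRUE),
      pCup = matrix(pv[2, ], out$h, out$w, byrow = TRUE),
      logits = list(disc = matrix(lv[1, ], out$h, out$w, byrow = TRUE),
                    cup = matrix(lv[2, ], out$h, out$w, byrow = TRUE)))
}

largest_component <- function(mask) {
  if (sum(mask) == 0) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) + 0
}

#' Predict binary disc and cup masks
#'
#' Thresholds the probability maps at `threshold`, keeps the largest
#' connected component per structure, and flags empty predictions instead of
#' raising. The network does not architecturally enforce cup-inside-disc;
#' `clip_cup = TRUE` optionally intersects the cup with the disc.
#'
#' @inheritParams encodeImage
#' @param threshold probability threshold (default from the model config).
#' @param clip_cup intersect the cup prediction with the disc prediction
#'   (default `FALSE`; evaluation counts stray cup pixels as errors).
#' @return a list of class `SegPrediction`: `disc`, `cup` (binary matrices),
#'   `prob` (the [MaskPair-class]), and `empty` (named logical flags).
#' @export
predictMasks <- function(model, image, threshold = model$config$threshold,
                         clip_cup = FALSE) {
  mp <- decodeImage(model, image)
  disc <- (discProb(mp) > threshold) + 0
  cup <- (cupProb(mp) > threshold) + 0
  empty <- c(disc = sum(disc) == 0, cup = sum(cup) == 0)
  disc <- largest_component(disc)
  cup <- largest_component(cup)
  if (clip_cup) cup <- cup * disc
  structure(list(disc = disc, cup = cup, prob = mp, empty = empty),
            class = "SegPrediction")
}

#' @export
print.SegPrediction <- function(x, ...) {
  cat(sprintf("SegPrediction: disc %d px%s, cup %d px%s\n",
              sum(x$disc), if (x$empty["disc"]) " (empty warning)" else "",
              sum(x$cup), if (x$empty["cup"]) " (empty warning)" else ""))
  invisible(x)
}

## ---- checkpoints ----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single archive holding the configuration, all parameter
#' values and a format-version string.
#'
#' @param model a `segnet` model.
#' @param path checkpoint file path.
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(version = "odcseg-ckpt-1", config = model$config,
              params = lapply(model$params, function(p) p$value))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "odcseg-ckpt-1"))
    stop("unrecognized checkpoint format: ", obj$version)
  model <- segNet(obj$config)
  for (nm in names(obj$params)) {
    if (is.null(model$params[[nm]])) {
      if (!startsWith(nm, "ssl."))
        stop("checkpoint parameter ", nm, " not present in the model")
      reg_param(model, nm, obj$params[[nm]])  # projection head, if saved
    } else {
      model$params[[nm]]$value <- obj$params[[nm]]
    }
  }
  model
}

## ---- Adam optimizer -------------------------------------------------------

adam_new <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p$value * 0)   # moment buffers keep shape
  opt$v <- lapply(params, function(p) p$value * 0)
  opt
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

adam_step <- function(opt, lr = opt$lr, clip_norm = NULL) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  scale <- 1
  if (!is.null(clip_norm)) {
    # global gradient-norm clipping: the rim term's log gradient can spike
    # while the disc-cup margin is still near the clamp boundary
    sq <- 0
    for (p in opt$params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
    gn <- sqrt(sq)
    if (gn > clip_norm) scale <- clip_norm / gn
  }
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (scale != 1) g <- g * scale
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    p$value <- p$value - lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
    p$grad <- NULL
  }
  invisible(opt)
}
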