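# Synthetic fundus-like scene generator: a bright elliptical optic disc
# containing a brighter elliptical cup on a textured red-orange background
# with dark curvilinear vessel-like distractors. Ground-truth masks are exact
# ellipse rasterizations, so every other module is testable without any
# downloaded data.

#' Scene parameters for one synthetic fundus sample
#'
#' @param image_size canvas side in pixels (default 128; sizes up to 512 are
#'   supported).
#' @param disc_center numeric `(row, col)` of the disc center in pixels
#'   (0-based; default: canvas center).
#' @param disc_axes numeric `(semi_vertical, semi_horizontal)` disc semi-axes
#'   in pixels.
#' @param disc_rotation rotation of the disc ellipse in degrees.
#' @param cup_scale fraction in `(0, 1)` applied to the disc axes to obtain
#'   the cup axes. The default 0.4 reflects the upper end of the normal
#'   vertical cup-to-disc ratio range (0.3-0.4).
#' @param cup_offset numeric `(row, col)` displacement of the cup center from
#'   the disc center, constrained so the cup stays inside the disc.
#' @param vessel_count number of vessel-like dark curves (default 6).
#' @param noise_sd standard deviation of the additive Gaussian intensity
#'   noise (default 0.02).
#' @param seed integer seed; the same parameters and seed yield bit-identical
#'   images and masks.
#' @return a list of class `SceneParams`.
#' @export
sceneParams <- function(image_size = 128L, disc_center = NULL,
                        disc_axes = NULL, disc_rotation = 0,
                        cup_scale = 0.4, cup_offset = c(0, 0),
                        vessel_count = 6L, noise_sd = 0.02, seed = 0L) {
  image_size <- as.integer(image_size)
  if (is.null(disc_center)) disc_center <- rep((image_size - 1) / 2, 2)
  if (is.null(disc_axes)) disc_axes <- image_size * c(0.22, 0.19)
  p <- structure(list(image_size = image_size, disc_center = disc_center,
                      disc_axes = disc_axes, disc_rotation = disc_rotation,
                      cup_scale = cup_scale, cup_offset = cup_offset,
                      vessel_count = as.integer(vessel_count),
                      noise_sd = noise_sd, seed = as.integer(seed)),
                 class = "SceneParams")
  validate_scene(p)
  p
}

#' @export
print.SceneParams <- function(x, ...) {
  cat(sprintf(
    "SceneParams: %dpx canvas, disc axes (%.1f, %.1f) rot %.0f deg, cup scale %.2f, seed %d\n",
    x$image_size, x$disc_axes[1], x$disc_axes[2], x$disc_rotation,
    x$cup_scale, x$seed))
  invisible(x)
}

#' Randomized scene parameters for dataset generation
#'
#' Draws jittered scene parameters (disc position, axes, rotation, cup scale
#' and offset, vessel count) from ranges that keep the geometry valid, using
#' the supplied seed for both the parameter draw and the subsequent
#' rendering.
#'
#' @inheritParams sceneParams
#' @export
randomSceneParams <- function(seed, image_size = 128L) {
  with_seed(seed, {
    s <- image_size
    ctr <- (s - 1) / 2 + runif(2, -0.06, 0.06) * s
    ax <- s * c(runif(1, 0.18, 0.24), runif(1, 0.15, 0.21))
    rot <- runif(1, 0, 180)
    cs <- runif(1, 0.3, 0.55)
    # keep the offset small relative to the free margin inside the disc
    off <- runif(2, -1, 1) * min(ax) * (1 - cs) * 0.3
    sceneParams(image_size = s, disc_center = ctr, disc_axes = ax,
                disc_rotation = rot, cup_scale = cs, cup_offset = off,
                vessel_count = sample(4:8, 1), seed = seed)
  })
}

# row/col grids have pixel centers at integer coordinates, 0-based
ellipse_mask <- function(size, center, axes, rotation = 0) {
  r <- matrix(0:(size - 1), size, size)
  cc <- matrix(0:(size - 1), size, size, byrow = TRUE)
  th <- rotation * pi / 180
  dr <- r - center[1]; dc <- cc - center[2]
  u <- cos(th) * dr + sin(th) * dc
  v <- -sin(th) * dr + cos(th) * dc
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

ellipse_boundary <- function(center, axes, rotation = 0, n = 360L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  th <- rotation * pi / 180
  u <- axes[1] * cos(t); v <- axes[2] * sin(t)
  cbind(row = center[1] + cos(th) * u - sin(th) * v,
        col = center[2] + sin(th) * u + cos(th) * v)
}

validate_scene <- function(p) {
  if (p$cup_scale <= 0 || p$cup_scale >= 1)
    stop("invalid geometry: cup_scale must lie in (0, 1)")
  if (any(p$disc_axes <= 0))
    stop("invalid geometry: disc axes must be positive")
  bd <- ellipse_boundary(p$disc_center, p$disc_axes, p$disc_rotation)
  if (min(bd) < 0 || max(bd) > p$image_size - 1)
    stop("invalid geometry: disc ellipse does not fit inside the canvas")
  cup_center <- p$disc_center + p$cup_offset
  bc <- ellipse_boundary(cup_center, p$cup_scale * p$disc_axes, p$disc_rotation)
  th <- p$disc_rotation * pi / 180
  dr <- bc[, 1] - p$disc_center[1]; dc <- bc[, 2] - p$disc_center[2]
  u <- cos(th) * dr + sin(th) * dc
  v <- -sin(th) * dr + cos(th) * dc
  if (any((u / p$disc_axes[1])^2 + (v / p$disc_axes[2])^2 > 1))
    stop("invalid geometry: cup ellipse crosses the disc boundary")
  invisible(TRUE)
}

# quadratic Bezier vessel curve stamped onto the image
draw_vessel <- function(img, size) {
  edge_point <- function() {
    side <- sample.int(4L, 1L)
    t <- runif(1, 0, size - 1)
    switch(side, c(0, t), c(size - 1, t), c(t, 0), c(t, size - 1))
  }
  p0 <- edge_point(); p2 <- edge_point()
  ctr <- (size - 1) / 2 + runif(2, -0.2, 0.2) * size
  tt <- seq(0, 1, length.out = 4L * size)
  pts <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), ctr) +
    outer(tt^2, p2)
  rr <- round(pts[, 1]); cc <- round(pts[, 2])
  keep <- rr >= 0 & rr < size & cc >= 0 & cc < size
  half <- sample(0:1, 1L)
  col_v <- c(0.33, 0.11, 0.08)
  alpha <- 0.85
  m <- matrix(FALSE, size, size)
  for (dr in -half:half) for (dc in -half:half) {
    r2 <- rr[keep] + dr; c2 <- cc[keep] + dc
    ok <- r2 >= 0 & r2 < size & c2 >= 0 & c2 < size
    m[cbind(r2[ok] + 1L, c2[ok] + 1L)] <- TRUE
  }
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[m] <- pl[m] * (1 - alpha) + col_v[ch] * alpha
    img[, , ch] <- pl
  }
  img
}

#' Render one synthetic fundus sample
#'
#' Renders the scene described by `params`: a textured red-orange background,
#' a bright elliptical disc, a brighter elliptical cup (background < disc <
#' cup in the green channel), vessel-like dark curves, a slight blur of the
#' anatomy for soft edges, and additive Gaussian noise. Masks are exact
#' ellipse rasterizations of the pre-blur geometry and always satisfy
#' cup subset-of disc.
#'
#' @param params a `SceneParams` object from [sceneParams()] or
#'   [randomSceneParams()].
#' @param id sample identifier stored in the result.
#' @param labeled if `FALSE`, the masks are omitted (unlabeled pool).
#' @return a [FundusImage-class].
#' @export
makeSample <- function(params = sceneParams(), id = "sample", labeled = TRUE) {
  validate_scene(params)
  s <- params$image_size
  disc <- ellipse_mask(s, params$disc_center, params$disc_axes,
                       params$disc_rotation)
  cup <- ellipse_mask(s, params$disc_center + params$cup_offset,
                      params$cup_scale * params$disc_axes,
                      params$disc_rotation)
  cup <- cup & disc   # guaranteed by validate_scene; belt and braces
  img <- with_seed(params$seed, {
    base <- c(0.66, 0.34, 0.18)
    img <- array(0, c(s, s, 3))
    # low-frequency background texture
    gr <- matrix(0:(s - 1), s, s) / s
    gc <- matrix(0:(s - 1), s, s, byrow = TRUE) / s
    tex <- 0
    for (j in 1:3) {
      fr <- runif(2, 1, 4); ph <- runif(2, 0, 2 * pi)
      tex <- tex + sin(2 * pi * fr[1] * gr + ph[1]) *
        sin(2 * pi * fr[2] * gc + ph[2])
    }
    tex <- tex / 3 * 0.05
    disc_col <- c(0.93, 0.78, 0.45)
    cup_col <- c(0.98, 0.90, 0.60)
    for (ch in 1:3) {
      pl <- base[ch] + tex
      pl[disc] <- disc_col[ch]
      pl[cup] <- cup_col[ch]
      img[, , ch] <- pl
    }
    img <- blurImage(img, 0.7)
    for (v in seq_len(params$vessel_count)) img <- draw_vessel(img, s)
    if (params$noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, params$noise_sd), dim(img))
    clip01(img)
  })
  if (labeled)
    new("FundusImage", pixels = img, discMask = disc + 0, cupMask = cup + 0,
        id = id, params = unclass(params))
  else
    new("FundusImage", pixels = img, id = id, params = unclass(params))
}

## ---- PNG + manifest I/O ---------------------------------------------------

# masks share one single-channel PNG: 0 background, 128 disc-only, 255 cup
write_mask_png <- function(disc, cup, path) {
  enc <- matrix(0, nrow(disc), ncol(disc))
  enc[disc == 1] <- 128 / 255
  enc[cup == 1] <- 1
  png::writePNG(enc, path)
}

read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  lv <- round(v * 255)
  list(disc = (lv >= 128) + 0, cup = (lv == 255) + 0)
}

#' Write a synthetic dataset to disk
#'
#' Renders `n` samples with randomized scene parameters and writes 8-bit RGB
#' image PNGs, three-level mask PNGs (0 = background, 128 = disc-only,
#' 255 = cup; omitted for the unlabeled split) and a YAML manifest listing
#' ids, per-sample parameters and the split. Re-running with the same
#' arguments reproduces byte-identical files.
#'
#' @param n number of samples (>= 1).
#' @param split one of `"train"`, `"val"`, `"unlabeled"`.
#' @param seed integer seed controlling every sample.
#' @param out_dir output directory (created if needed).
#' @param force overwrite an existing manifest (default `FALSE`).
#' @param image_size canvas side in pixels.
#' @return the manifest path, invisibly.
#' @export
makeDataset <- function(n, split = c("train", "val", "unlabeled"), seed,
                        out_dir, force = FALSE, image_size = 128L) {
  split <- match.arg(split)
  stopifnot(n >= 1)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (file.exists(manifest_path) && !force)
    stop("manifest already exists at ", manifest_path,
         "; use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labeled <- split != "unlabeled"
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("%s_%03d", split, i)
    sseed <- (as.integer(seed) * 1009L + i * 101L) %% 2000000000L
    par <- randomSceneParams(sseed, image_size = image_size)
    fi <- makeSample(par, id = sid, labeled = labeled)
    img_file <- paste0(sid, ".png")
    png::writePNG(imagePixels(fi), file.path(out_dir, img_file))
    entry <- list(id = sid, image = img_file,
                  params = lapply(unclass(par), function(x)
                    if (is.numeric(x)) as.numeric(x) else x))
    if (labeled) {
      mask_file <- paste0(sid, "_mask.png")
      write_mask_png(discMask(fi), cupMask(fi), file.path(out_dir, mask_file))
      entry$mask <- mask_file
    }
    samples[[i]] <- entry
  }
  yaml::write_yaml(list(split = split, seed = as.integer(seed), n = n,
                        image_size = as.integer(image_size),
                        samples = samples), manifest_path)
  invisible(manifest_path)
}

#' Load a dataset manifest
#'
#' Reads the YAML manifest written by [makeDataset()] and returns the listed
#' samples as [FundusImage-class] objects (masks decoded from the 0/128/255
#' PNG convention when present).
#'
#' @param manifest_path path to `manifest.yaml`.
#' @return a list of `FundusImage` objects.
#' @export
loadManifest <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  lapply(man$samples, function(e) {
    img <- png::readPNG(file.path(dir, e$image))
    if (!is.null(e$mask)) {
      mk <- read_mask_png(file.path(dir, e$mask))
      new("FundusImage", pixels = img, discMask = mk$disc, cupMask = mk$cup,
          id = e$id, params = if (is.null(e$params)) list() else e$params)
    } else {
      new("FundusImage", pixels = img, id = e$id,
          params = if (is.null(e$params)) list() else e$params)
    }
  })
}
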