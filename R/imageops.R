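# Plain-array image utilities: separable Gaussian blur, kernel sharpening,
# gamma contrast, exact quarter-turn rotation, and bilinear resizing.
# Images are H x W (matrix) or H x W x 3 arrays with intensities in [0, 1].

clip01 <- function(x) pmin(pmax(x, 0), 1)

shift_rows <- function(m, d) {
  m[pmin(pmax(seq_len(nrow(m)) + d, 1L), nrow(m)), , drop = FALSE]
}
shift_cols <- function(m, d) {
  m[, pmin(pmax(seq_len(ncol(m)) + d, 1L), ncol(m)), drop = FALSE]
}

gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w / sum(w)
}

blur_channel <- function(m, sigma) {
  k <- gauss_kernel1d(sigma)
  if (length(k) == 1L) return(m)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * shift_rows(m, j - r - 1L)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * shift_cols(m2, j - r - 1L)
  out
}

# edge-replicated separable Gaussian blur
blurImage <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (is.matrix(img)) return(blur_channel(img, sigma))
  for (ch in seq_len(dim(img)[3])) img[, , ch] <- blur_channel(img[, , ch], sigma)
  img
}

# 3x3 kernel sharpening (0,-1,0 / -1,5,-1 / 0,-1,0), edge-replicated
sharpen_channel <- function(m) {
  5 * m - shift_rows(m, -1L) - shift_rows(m, 1L) -
    shift_cols(m, -1L) - shift_cols(m, 1L)
}
sharpenImage <- function(img) {
  if (is.matrix(img)) return(clip01(sharpen_channel(img)))
  for (ch in seq_len(dim(img)[3])) img[, , ch] <- sharpen_channel(img[, , ch])
  clip01(img)
}

# counter-clockwise quarter turns (k in 0..3)
rot90_channel <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}
rotateImage <- function(img, k) {
  k <- k %% 4L
  if (k == 0L) return(img)
  if (is.matrix(img)) return(rot90_channel(img, k))
  d <- dim(img)
  nd <- if (k %% 2L == 1L) c(d[2], d[1], d[3]) else d
  out <- array(0, nd)
  for (ch in seq_len(d[3])) out[, , ch] <- rot90_channel(img[, , ch], k)
  out
}

# 1-d bilinear interpolation matrix (align_corners = FALSE, edge-clamped)
interp_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  f <- src - i0
  f[i0 < 0] <- 0
  i0 <- pmin(pmax(i0, 0), n_in - 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  for (r in seq_len(n_out)) {
    M[r, i0[r] + 1] <- M[r, i0[r] + 1] + (1 - f[r])
    M[r, i1[r] + 1] <- M[r, i1[r] + 1] + f[r]
  }
  M
}

resizeImage <- function(img, h_out, w_out) {
  one <- function(m) {
    Rm <- interp_matrix(nrow(m), h_out)
    Cm <- interp_matrix(ncol(m), w_out)
    Rm %*% m %*% t(Cm)
  }
  if (is.matrix(img)) return(one(img))
  out <- array(0, c(h_out, w_out, dim(img)[3]))
  for (ch in seq_len(dim(img)[3])) out[, , ch] <- one(img[, , ch])
  out
}

# fold an H x W x C image into the network's C x (H*W) row-major token layout
image_to_cmat <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  out <- matrix(0, d[3], d[1] * d[2])
  for (ch in seq_len(d[3])) out[ch, ] <- as.vector(t(img[, , ch]))
  out
}
cmat_to_image <- function(m, h, w) {
  C <- nrow(m)
  out <- array(0, c(h, w, C))
  for (ch in seq_len(C)) out[, , ch] <- matrix(m[ch, ], h, w, byrow = TRUE)
  if (C == 1L) out[, , 1L] else out
}
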