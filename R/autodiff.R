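# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Nodes are environments holding a value, a list of parent nodes and a
# backward closure mapping the node's gradient to gradients for each parent.
# The tape is implicit: node ids increase monotonically with creation, and
# creation order is a topological order of the forward graph, so the backward
# sweep just visits reachable nodes by decreasing id.

.ad <- new.env(parent = emptyenv())
.ad$n <- 0L
.ad$cache <- new.env(parent = emptyenv())   # shape-indexed prep (conv/upsample)

new_node <- function(value, parents = list(), backfn = NULL, needs = FALSE) {
  .ad$n <- .ad$n + 1L
  nd <- new.env(parent = emptyenv())
  nd$id <- .ad$n
  nd$value <- value
  nd$parents <- parents
  nd$backfn <- backfn
  nd$needs <- needs ||
    any(vapply(parents, function(p) p$needs, logical(1)))
  nd$grad <- NULL
  class(nd) <- "ad_node"
  nd
}

nd_const <- function(x) new_node(x)
nd_param <- function(x) {
  nd <- new_node(x, needs = TRUE)
  nd$param <- TRUE
  nd
}
as_node  <- function(x) if (inherits(x, "ad_node")) x else nd_const(x)
is_node  <- function(x) inherits(x, "ad_node")
nd_value <- function(x) if (is_node(x)) x$value else x

# Backward sweep from a scalar (or explicitly seeded) root.
nd_backward <- function(root, grad = NULL) {
  stopifnot(is_node(root))
  if (is.null(grad)) {
    v <- root$value
    grad <- if (is.null(dim(v))) rep(1, length(v)) else array(1, dim(v))
  }
  # collect reachable grad-requiring nodes
  stack <- list(root)
  seen <- new.env(parent = emptyenv())
  nodes <- list()
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (p$needs) stack[[length(stack) + 1L]] <- p
  }
  for (nd in nodes) nd$grad <- NULL
  root$grad <- grad
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  for (i in ord) {
    nd <- nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!p$needs || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    # intermediate gradients are consumed here; only parameter nodes keep
    # theirs (for the optimizer), which caps the live memory of large tapes
    if (!isTRUE(nd$param)) nd$grad <- NULL
  }
  invisible(root)
}

# scatter-add columns of g into a zero C x P matrix at (possibly repeated) idx
scatter_add_cols <- function(C, P, idx, g) {
  ag <- rowsum(t(g), group = idx)
  out <- matrix(0, C, P)
  out[, as.integer(rownames(ag))] <- t(ag)
  out
}

## ---- elementwise / linear algebra ----------------------------------------

nd_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  if (is.matrix(av) && !is.matrix(bv) && length(bv) == nrow(av)) {
    # column-broadcast bias (length-C vector added to C x P matrix)
    new_node(av + bv, list(a, b), function(g) list(g, rowSums(g)))
  } else {
    stopifnot(length(av) == length(bv))
    new_node(av + bv, list(a, b), function(g) list(g, g))
  }
}

nd_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  stopifnot(length(a$value) == length(b$value))
  new_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

nd_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  stopifnot(length(av) == length(bv))
  new_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

nd_scale <- function(a, s) {
  a <- as_node(a)
  new_node(a$value * s, list(a), function(g) list(g * s))
}

nd_mm <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  new_node(av %*% bv, list(a, b),
           function(g) list(tcrossprod(g, bv), crossprod(av, g)))
}

# t(a) %*% b without materializing the transpose
nd_crossprod <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  new_node(crossprod(av, bv), list(a, b),
           function(g) list(tcrossprod(bv, g), av %*% g))
}

# a %*% t(b) without materializing the transpose
nd_tcrossprod <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  av <- a$value; bv <- b$value
  new_node(tcrossprod(av, bv), list(a, b),
           function(g) list(g %*% bv, crossprod(g, av)))
}

nd_t <- function(a) {
  a <- as_node(a)
  new_node(t(a$value), list(a), function(g) list(t(g)))
}

nd_relu <- function(a) {
  a <- as_node(a)
  m <- a$value > 0
  new_node(a$value * m, list(a), function(g) list(g * m))
}

nd_sigmoid <- function(a) {
  a <- as_node(a)
  s <- 1 / (1 + exp(-a$value))
  new_node(s, list(a), function(g) list(g * s * (1 - s)))
}

nd_exp <- function(a) {
  a <- as_node(a)
  e <- exp(a$value)
  new_node(e, list(a), function(g) list(g * e))
}

nd_log <- function(a) {
  a <- as_node(a)
  v <- a$value
  new_node(log(v), list(a), function(g) list(g / v))
}

nd_clamp <- function(a, lo, hi) {
  a <- as_node(a)
  v <- a$value
  open <- v > lo & v < hi
  new_node(pmin(pmax(v, lo), hi), list(a), function(g) list(g * open))
}

nd_sum <- function(a) {
  a <- as_node(a)
  v <- a$value
  dm <- dim(v)
  new_node(sum(v), list(a), function(g) {
    list(if (is.null(dm)) rep(g, length(v)) else array(g, dm))
  })
}

nd_mean <- function(a) {
  a <- as_node(a)
  v <- a$value
  n <- length(v)
  dm <- dim(v)
  new_node(sum(v) / n, list(a), function(g) {
    list(if (is.null(dm)) rep(g / n, n) else array(g / n, dm))
  })
}

nd_rowsums <- function(a) {
  a <- as_node(a)
  v <- a$value
  new_node(rowSums(v), list(a), function(g) {
    list(matrix(g, nrow(v), ncol(v)))
  })
}

# softmax along each row of a matrix; a global max shift is enough for
# overflow safety at the score magnitudes attention produces
nd_softmax_rows <- function(a) {
  a <- as_node(a)
  v <- a$value
  e <- exp(v - max(v))
  A <- e / rowSums(e)
  new_node(A, list(a), function(g) {
    list(A * (g - rowSums(g * A)))
  })
}

## ---- indexing / shaping ---------------------------------------------------

nd_gather_cols <- function(a, idx) {
  a <- as_node(a)
  v <- a$value
  C <- nrow(v); P <- ncol(v)
  idx <- as.integer(idx)
  new_node(v[, idx, drop = FALSE], list(a), function(g) {
    list(scatter_add_cols(C, P, idx, g))
  })
}

# pick scattered elements a[cbind(i, j)]; (i, j) pairs must be distinct
nd_gather_elems <- function(a, ij) {
  a <- as_node(a)
  v <- a$value
  new_node(v[ij], list(a), function(g) {
    out <- array(0, dim(v)); out[ij] <- g; list(out)
  })
}

nd_rbind <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  vals <- lapply(nodes, function(n) n$value)
  rows <- vapply(vals, nrow, integer(1))
  ends <- cumsum(rows)
  starts <- c(1L, head(ends, -1L) + 1L)
  new_node(do.call(rbind, vals), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

nd_rows <- function(a, rows) {
  a <- as_node(a)
  v <- a$value
  new_node(v[rows, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(v), ncol(v)); out[rows, ] <- g; list(out)
  })
}

nd_reshape <- function(a, dims) {
  a <- as_node(a)
  old <- dim(a$value)
  if (is.null(old)) old <- length(a$value)
  new_node(array(a$value, dims), list(a), function(g) list(array(g, old)))
}

# max over groups of K consecutive columns: C x (P*K) -> C x P
# (columns (p-1)*K + 1 .. p*K belong to group p); ties keep the first member
nd_max_groupcols <- function(a, K) {
  a <- as_node(a)
  v <- a$value
  stopifnot(ncol(v) %% K == 0L)
  r <- cpp_group_max(v, as.integer(K))
  new_node(r$max, list(a), function(g) {
    list(cpp_group_max_bwd(g, r$argk, as.integer(K)))
  })
}

## ---- normalization --------------------------------------------------------

# LayerNorm over the channel (row) axis, independently per column/token.
# gamma, beta: length-C vectors.
nd_layernorm_cols <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  v <- x$value
  C <- nrow(v)
  mu <- colMeans(v)
  xc <- v - rep(mu, each = C)
  va <- colMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  invm <- rep(inv, each = C)
  xhat <- xc * invm
  gv <- gamma$value
  y <- xhat * gv + beta$value   # column recycling of length-C vectors
  new_node(y, list(x, gamma, beta), function(g) {
    gy <- g * gv
    m1 <- colMeans(gy)
    m2 <- colMeans(gy * xhat)
    dx <- (gy - rep(m1, each = C) - xhat * rep(m2, each = C)) * invm
    list(dx, rowSums(g * xhat), rowSums(g))
  })
}

# GroupNorm over contiguous row groups of a C x P map (statistics over group
# rows x all positions); gamma, beta length-C. Group statistics come from
# row sums, and the per-group scalars are expanded to length C so every
# array operation stays vectorized with column-major recycling.
nd_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  v <- x$value
  C <- nrow(v); P <- ncol(v)
  stopifnot(C %% groups == 0L)
  gsz <- C %/% groups
  gid <- rep(seq_len(groups), each = gsz)
  n_g <- gsz * P
  group_mean <- function(m) {
    as.vector(rowsum(rowSums(m), gid, reorder = FALSE)) / n_g
  }
  mu <- group_mean(v)
  va <- group_mean(v * v) - mu^2
  inv <- 1 / sqrt(va + eps)
  muc <- rep(mu, each = gsz)     # length-C, recycled down columns
  invc <- rep(inv, each = gsz)
  xhat <- (v - muc) * invc
  gv <- gamma$value
  y <- xhat * gv + beta$value
  new_node(y, list(x, gamma, beta), function(g) {
    gy <- g * gv
    m1 <- rep(group_mean(gy), each = gsz)
    m2 <- rep(group_mean(gy * xhat), each = gsz)
    dx <- (gy - m1 - xhat * m2) * invc
    list(dx, rowSums(g * xhat), rowSums(g))
  })
}

# L2-normalize each column
nd_l2norm_cols <- function(x, eps = 1e-12) {
  x <- as_node(x)
  v <- x$value
  C <- nrow(v)
  n <- sqrt(colSums(v^2) + eps)
  nm <- rep(n, each = C)
  y <- v / nm
  new_node(y, list(x), function(g) {
    dot <- colSums(g * y)
    list((g - y * rep(dot, each = C)) / nm)
  })
}

## ---- spatial ops (feature maps are C x (h*w), row-major positions) --------

# position (r, c), 0-based -> column r*w + c + 1

conv_prep <- function(h, w, k, stride, pad) {
  key <- paste("conv", h, w, k, stride, pad, sep = "_")
  hit <- .ad$cache[[key]]
  if (!is.null(hit)) return(hit)
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  ro <- rep(0:(ho - 1L), each = wo)
  co <- rep(0:(wo - 1L), times = ho)
  k2 <- k * k
  idx <- matrix(0L, k2, ho * wo)
  j <- 0L
  for (kr in 0:(k - 1L)) for (kc in 0:(k - 1L)) {
    j <- j + 1L
    ri <- ro * stride - pad + kr
    ci <- co * stride - pad + kc
    ok <- ri >= 0L & ri < h & ci >= 0L & ci < w
    ii <- integer(ho * wo)
    ii[ok] <- ri[ok] * w + ci[ok] + 1L
    idx[j, ] <- ii
  }
  out <- list(idx = idx, ho = ho, wo = wo, k = k, k2 = k2)
  .ad$cache[[key]] <- out
  out
}

im2col <- function(v, prep, Cin) {
  cpp_im2col(v, prep$idx)
}

# x: Cin x (h*w); wgt: Cout x (Cin*k*k); b: length Cout
nd_conv2d <- function(x, wgt, b, h, w, stride = 1L, pad = NULL) {
  x <- as_node(x); wgt <- as_node(wgt); b <- as_node(b)
  v <- x$value
  Cin <- nrow(v)
  k2 <- ncol(wgt$value) / Cin
  k <- as.integer(round(sqrt(k2)))
  stopifnot(k * k * Cin == ncol(wgt$value))
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  prep <- conv_prep(h, w, k, as.integer(stride), as.integer(pad))
  cols <- im2col(v, prep, Cin)
  wv <- wgt$value
  y <- wv %*% cols + b$value
  nd <- new_node(y, list(x, wgt, b), function(g) {
    dW <- tcrossprod(g, cols)
    db <- rowSums(g)
    dcols <- crossprod(wv, g)
    dX <- cpp_col2im(dcols, prep$idx, ncol(v))
    list(dX, dW, db)
  })
  attr(nd, "ho") <- prep$ho
  attr(nd, "wo") <- prep$wo
  nd
}

upsample_prep <- function(h, w) {
  key <- paste("up", h, w, sep = "_")
  hit <- .ad$cache[[key]]
  if (!is.null(hit)) return(hit)
  ho <- 2L * h; wo <- 2L * w
  # align_corners = FALSE mapping: src = (out + 0.5)/2 - 0.5
  src_r <- (0:(ho - 1L) + 0.5) / 2 - 0.5
  src_c <- (0:(wo - 1L) + 0.5) / 2 - 0.5
  r0 <- pmax(pmin(floor(src_r), h - 1L), 0L); fr <- pmin(pmax(src_r - floor(src_r), 0), 1)
  c0 <- pmax(pmin(floor(src_c), w - 1L), 0L); fc <- pmin(pmax(src_c - floor(src_c), 0), 1)
  r1 <- pmin(r0 + 1L, h - 1L)
  c1 <- pmin(c0 + 1L, w - 1L)
  # handle edges where floor(src) < 0: frac should interpolate toward same pixel
  fr[floor(src_r) < 0] <- 0
  fc[floor(src_c) < 0] <- 0
  R0 <- rep(r0, each = wo); R1 <- rep(r1, each = wo); FR <- rep(fr, each = wo)
  C0 <- rep(c0, times = ho); C1 <- rep(c1, times = ho); FC <- rep(fc, times = ho)
  idx <- list(R0 * w + C0 + 1L, R0 * w + C1 + 1L,
              R1 * w + C0 + 1L, R1 * w + C1 + 1L)
  wts <- list((1 - FR) * (1 - FC), (1 - FR) * FC, FR * (1 - FC), FR * FC)
  out <- list(idx = idx, wts = wts, ho = ho, wo = wo)
  .ad$cache[[key]] <- out
  out
}

# bilinear x2 upsampling of a C x (h*w) map
nd_upsample2x <- function(x, h, w) {
  x <- as_node(x)
  v <- x$value
  C <- nrow(v)
  prep <- upsample_prep(h, w)
  y <- matrix(0, C, prep$ho * prep$wo)
  for (m in 1:4) {
    wm <- prep$wts[[m]]
    nz <- wm != 0
    if (!any(nz)) next
    y <- y + v[, prep$idx[[m]], drop = FALSE] *
      rep(wm, each = C)
  }
  nd <- new_node(y, list(x), function(g) {
    dX <- matrix(0, C, ncol(v))
    for (m in 1:4) {
      wm <- prep$wts[[m]]
      if (!any(wm != 0)) next
      dX <- dX + scatter_add_cols(C, ncol(v), prep$idx[[m]],
                                  g * rep(wm, each = C))
    }
    list(dX)
  })
  attr(nd, "ho") <- prep$ho
  attr(nd, "wo") <- prep$wo
  nd
}

# Dense interpolation matrix M (P_in x P_out) pooling the full-image box of an
# h x w map to an out x out grid, averaging sampling_ratio^2 bilinear samples
# per bin (RoiAlign with the whole image as the region).
roialign_matrix <- function(h, w, out = 24L, sampling = 2L) {
  key <- paste("roi", h, w, out, sampling, sep = "_")
  hit <- .ad$cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- matrix(0, h * w, out * out)
  bin_h <- h / out
  bin_w <- w / out
  for (br in 0:(out - 1L)) for (bc in 0:(out - 1L)) {
    col <- br * out + bc + 1L
    for (sr in seq_len(sampling)) for (sc in seq_len(sampling)) {
      yy <- br * bin_h + (sr - 0.5) * bin_h / sampling - 0.5
      xx <- bc * bin_w + (sc - 0.5) * bin_w / sampling - 0.5
      y0 <- floor(yy); x0 <- floor(xx)
      fy <- yy - y0; fx <- xx - x0
      for (dd in list(c(0, 0, (1 - fy) * (1 - fx)), c(0, 1, (1 - fy) * fx),
                      c(1, 0, fy * (1 - fx)), c(1, 1, fy * fx))) {
        rr <- min(max(y0 + dd[1], 0), h - 1L)
        cc <- min(max(x0 + dd[2], 0), w - 1L)
        M[rr * w + cc + 1L, col] <- M[rr * w + cc + 1L, col] +
          dd[3] / (sampling * sampling)
      }
    }
  }
  .ad$cache[[key]] <- M
  M
}

# RoiAlign pooling (full-image box) of C x (h*w) -> C x (out*out)
nd_roialign <- function(x, h, w, out = 24L, sampling = 2L) {
  M <- roialign_matrix(h, w, out, sampling)
  nd_mm(x, M)
}
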