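# Attention operators: the multi-scale KNN-attention block and the
# cluster-based aggregation attention block. All operators act on token
# matrices with channels as rows and positions as columns (see TokenTensor);
# node-level fw_* functions are shared between the exported array interface
# and the differentiable network path.

## ---- token folding --------------------------------------------------------

#' Fold a stack of feature maps into a token sequence
#'
#' Reshapes a `(B*N, C, h, w)` feature array into flattened patch tokens with
#' position index `p = n*h*w + r*w + c` (0-based, row-major), the layout used
#' by every attention operator in the package. The inverse,
#' [unflattenTokens()], restores the array exactly.
#'
#' @param x numeric 4-d array with dimensions `(B*N, C, h, w)`.
#' @param groupSize integer N, the number of feature-map groups folded into
#'   each token sequence.
#' @return A [TokenTensor-class] if the batch size is 1, otherwise a list of
#'   `TokenTensor` objects (one per batch element).
#' @examples
#' x <- array(rnorm(1 * 4 * 2 * 2), c(1, 4, 2, 2))
#' tt <- flattenTokens(x)
#' all.equal(unflattenTokens(tt), x)
#' @export
flattenTokens <- function(x, groupSize = 1L) {
  d <- dim(x)
  stopifnot(length(d) == 4L, d[1] %% groupSize == 0L)
  B <- d[1] %/% groupSize
  C <- d[2]; h <- d[3]; w <- d[4]
  out <- vector("list", B)
  for (b in seq_len(B)) {
    vals <- matrix(0, C, groupSize * h * w)
    for (n in seq_len(groupSize)) {
      m <- (b - 1L) * groupSize + n
      A <- array(x[m, , , ], c(C, h, w))
      vals[, ((n - 1L) * h * w + 1L):(n * h * w)] <-
        matrix(aperm(A, c(1, 3, 2)), C, h * w)
    }
    out[[b]] <- new("TokenTensor", values = vals,
                    gridShape = c(as.integer(h), as.integer(w)),
                    groupSize = as.integer(groupSize))
  }
  if (B == 1L) out[[1L]] else out
}

#' @rdname flattenTokens
#' @param tt a `TokenTensor` or list of them, as returned by [flattenTokens()].
#' @export
unflattenTokens <- function(tt) {
  if (is(tt, "TokenTensor")) tt <- list(tt)
  B <- length(tt)
  h <- tt[[1]]@gridShape[1]; w <- tt[[1]]@gridShape[2]
  N <- tt[[1]]@groupSize
  C <- nrow(tt[[1]]@values)
  x <- array(0, c(B * N, C, h, w))
  for (b in seq_len(B)) for (n in seq_len(N)) {
    block <- tt[[b]]@values[, ((n - 1L) * h * w + 1L):(n * h * w), drop = FALSE]
    x[(b - 1L) * N + n, , , ] <- aperm(array(block, c(C, w, h)), c(1, 3, 2))
  }
  x
}

token_matrix <- function(x) {
  if (is(x, "TokenTensor")) x@values else as.matrix(x)
}

## ---- similarity and neighbors --------------------------------------------

#' Cosine token similarity matrix
#'
#' Pairwise similarity of tokens, computed as the Gram matrix of the
#' L2-normalized channel vectors. The squared Euclidean distance between
#' normalized features is `2 - 2*S`, so ranking by this similarity is the
#' distance ranking with the constant removed.
#'
#' @param x a [TokenTensor-class] or a C x P matrix (channels x positions).
#' @return a symmetric P x P matrix with unit diagonal and entries in
#'   `[-1, 1]`.
#' @export
tokenSimilarity <- function(x) {
  v <- token_matrix(x)
  n <- sqrt(colSums(v^2))
  if (any(n < 1e-12))
    stop("degenerate feature: zero-norm channel vector at position ",
         which(n < 1e-12)[1])
  F <- sweep(v, 2L, n, `/`)
  S <- crossprod(F)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

topk_rows <- function(S, k) {
  cpp_topk_rows(S, as.integer(k))
}

#' Top-K most similar tokens per query
#'
#' For each query row of a similarity matrix, selects the `k` positions with
#' the largest similarity. The diagonal is maximal for cosine similarity, so
#' each query's neighbor set includes itself; ties are broken toward the
#' lower index for cross-platform determinism.
#'
#' @param S P x P similarity matrix (rows are queries).
#' @param k neighbor count, `1 <= k <= P`.
#' @return an object of class `NeighborIndex`: a list with `indices`
#'   (P x k integer matrix, 1-based positions in decreasing similarity) and
#'   `k`.
#' @export
topkNeighbors <- function(S, k) {
  P <- ncol(S)
  if (k > P) stop("k (", k, ") exceeds the number of positions (", P, ")")
  structure(list(indices = topk_rows(S, k), k = as.integer(k)),
            class = "NeighborIndex")
}

#' @export
print.NeighborIndex <- function(x, ...) {
  cat(sprintf("NeighborIndex: %d queries, k=%d\n", nrow(x$indices), x$k))
  invisible(x)
}

## ---- parameter initializers ----------------------------------------------

xavier_init <- function(nout, nin) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / (nin + nout))), nout, nin)
}

#' Parameters for the multi-scale attention block
#'
#' Creates the learnable state of one multi-scale attention block: pre-norm
#' LayerNorm scales, multi-head self-attention projections, and one
#' two-layer 1x1-convolution MLP (`phi`) per neighbor scale. The MHSA output
#' projection and each `phi`'s second layer start at zero so a freshly
#' initialized block is an exact identity (residual-branch zero init).
#'
#' @param C channel count; must be divisible by `heads`.
#' @param heads number of attention heads (default 4).
#' @param scales integer vector of KNN neighbor counts (default `c(4, 6, 8)`).
#' @param seed optional integer seed for reproducible initialization.
#' @return a named list of arrays understood by [multiScaleAttention()],
#'   [mhsaBlock()] and [msmlp()].
#' @export
attentionParams <- function(C, heads = 4L, scales = c(4L, 6L, 8L), seed = NULL) {
  if (C %% heads != 0L)
    stop("C (", C, ") must be divisible by heads (", heads, ")")
  with_seed(seed, {
    phi <- lapply(scales, function(k) {
      list(W1 = xavier_init(C, C), b1 = rep(0, C),
           W2 = matrix(0, C, C), b2 = rep(0, C))
    })
    names(phi) <- paste0("k", scales)
    list(heads = as.integer(heads), scales = as.integer(scales),
         ln1_g = rep(1, C), ln1_b = rep(0, C),
         Wq = xavier_init(C, C), bq = rep(0, C),
         Wk = xavier_init(C, C), bk = rep(0, C),
         Wv = xavier_init(C, C), bv = rep(0, C),
         Wo = matrix(0, C, C), bo = rep(0, C),
         ln2_g = rep(1, C), ln2_b = rep(0, C),
         phi = phi)
  })
}

#' Parameters for the aggregation attention block
#'
#' Single-head Q/K/V projections (`W x + B`) shared between the per-cluster
#' token attention and the centroid attention. The value projection starts at
#' zero, so a fresh block reduces to `input + broadcast centroid`.
#'
#' @inheritParams attentionParams
#' @return a named list of arrays understood by [aggregationAttention()].
#' @export
aggregationParams <- function(C, seed = NULL) {
  with_seed(seed, list(
    Wq = xavier_init(C, C), bq = rep(0, C),
    Wk = xavier_init(C, C), bk = rep(0, C),
    Wv = matrix(0, C, C), bv = rep(0, C)))
}

## ---- node-level forwards --------------------------------------------------

# multi-head self-attention with pre-norm and residual: MHSA(LN(x)) + x
fw_mhsa <- function(x, p, heads = NULL) {
  if (is.null(heads)) heads <- p$heads
  xn <- nd_layernorm_cols(x, p$ln1_g, p$ln1_b)
  C <- nrow(nd_value(xn))
  D <- C %/% heads
  Q <- nd_add(nd_mm(p$Wq, xn), p$bq)
  K <- nd_add(nd_mm(p$Wk, xn), p$bk)
  V <- nd_add(nd_mm(p$Wv, xn), p$bv)
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    rows <- ((h - 1L) * D + 1L):(h * D)
    Qh <- nd_rows(Q, rows); Kh <- nd_rows(K, rows); Vh <- nd_rows(V, rows)
    # fold the 1/sqrt(D) scale into the small Q factor
    A <- nd_softmax_rows(nd_crossprod(nd_scale(Qh, 1 / sqrt(D)), Kh))
    outs[[h]] <- nd_tcrossprod(Vh, A)
  }
  cat_heads <- if (heads == 1L) outs[[1L]] else nd_rbind(outs)
  nd_add(nd_add(nd_mm(p$Wo, cat_heads), p$bo), x)
}

# multi-scale KNN MLP: for each scale k, gather each token's k most similar
# tokens, apply phi (1x1 conv, ReLU, 1x1 conv), max-reduce over neighbors,
# and sum the per-scale outputs. Neighbor selection is treated as constant
# (no gradient flows through the ranking).
fw_msmlp <- function(x, p, scales = NULL, clip_scales = FALSE) {
  if (is.null(scales)) scales <- p$scales
  v <- nd_value(x)
  P <- ncol(v)
  if (clip_scales) scales <- unique(pmin(scales, P))
  if (max(scales) > P)
    stop("largest neighbor scale (", max(scales), ") exceeds P (", P, ")")
  n <- sqrt(colSums(v^2) + 1e-12)
  S <- crossprod(v / rep(n, each = nrow(v)))
  idx <- cpp_topk_sym(S, max(scales))   # S is symmetric: columns are rows
  acc <- NULL
  for (si in seq_along(scales)) {
    k <- scales[si]
    pp <- p$phi[[si]]
    cols <- as.vector(t(idx[, seq_len(k), drop = FALSE]))
    xhat <- nd_gather_cols(x, cols)
    h1 <- nd_relu(nd_add(nd_mm(pp$W1, xhat), pp$b1))
    h2 <- nd_add(nd_mm(pp$W2, h1), pp$b2)
    m <- nd_max_groupcols(h2, as.integer(k))
    acc <- if (is.null(acc)) m else nd_add(acc, m)
  }
  acc
}

# full multi-scale attention block: X' = MHSA(LN(X)) + X;
# out = MSMLP(LN(X')) + X'
fw_ms_attention <- function(x, p, clip_scales = FALSE) {
  x1 <- fw_mhsa(x, p)
  ms <- fw_msmlp(nd_layernorm_cols(x1, p$ln2_g, p$ln2_b), p,
                 clip_scales = clip_scales)
  nd_add(ms, x1)
}

# aggregation attention: cluster tokens (k-means over normalized features),
# run scaled attention within each cluster and over the centroid sequence,
# broadcast updated centroids back to members and add.
fw_aggregation <- function(x, p, clusters = 3L, seed = NULL) {
  v <- nd_value(x)
  C <- nrow(v); P <- ncol(v)
  cs <- clusterAssign(v, clusters = clusters, seed = seed)
  labels <- cs$labels
  Q <- nd_add(nd_mm(p$Wq, x), p$bq)
  K <- nd_add(nd_mm(p$Wk, x), p$bk)
  V <- nd_add(nd_mm(p$Wv, x), p$bv)
  sD <- 1 / sqrt(C)
  upd_sum <- NULL
  Mavg <- matrix(0, P, clusters)
  Bind <- matrix(0, P, clusters)
  cent_fix <- matrix(0, C, clusters)   # constant columns for empty clusters
  for (g in seq_len(clusters)) {
    mem <- which(labels == g)
    Bind[mem, g] <- 1
    if (length(mem) == 0L) {
      cent_fix[, g] <- cs$centroids[g, ]
      next
    }
    Mavg[mem, g] <- 1 / length(mem)
    Qg <- nd_gather_cols(Q, mem)
    Kg <- nd_gather_cols(K, mem)
    Vg <- nd_gather_cols(V, mem)
    A <- nd_softmax_rows(nd_scale(nd_crossprod(Qg, Kg), sD))
    # scatter member updates back to their positions
    scat <- matrix(0, length(mem), P)
    scat[cbind(seq_along(mem), mem)] <- 1
    upd <- nd_mm(nd_tcrossprod(Vg, A), scat)
    upd_sum <- if (is.null(upd_sum)) upd else nd_add(upd_sum, upd)
  }
  members_out <- if (is.null(upd_sum)) x else nd_add(x, upd_sum)
  # centroids of normalized token features (differentiable recompute)
  xn <- nd_l2norm_cols(x)
  cent <- nd_mm(xn, Mavg)
  if (any(cent_fix != 0)) cent <- nd_add(cent, cent_fix)
  Qc <- nd_add(nd_mm(p$Wq, cent), p$bq)
  Kc <- nd_add(nd_mm(p$Wk, cent), p$bk)
  Vc <- nd_add(nd_mm(p$Wv, cent), p$bv)
  Ac <- nd_softmax_rows(nd_scale(nd_crossprod(Qc, Kc), sD))
  cent_out <- nd_add(cent, nd_tcrossprod(Vc, Ac))
  nd_add(members_out, nd_mm(cent_out, t(Bind)))
}

## ---- exported array interface --------------------------------------------

#' Multi-head self-attention block
#'
#' Computes `MHSA(LN(x)) + x` (pre-norm residual). Output shape equals input
#' shape.
#'
#' @param x a [TokenTensor-class] or C x P matrix.
#' @param params parameters from [attentionParams()].
#' @return a C x P matrix.
#' @export
mhsaBlock <- function(x, params) {
  nd_value(fw_mhsa(nd_const(token_matrix(x)), params))
}

#' Multi-scale KNN multilayer perceptron
#'
#' For each neighbor scale `k`, gathers each token's `k` most similar tokens
#' (cosine similarity of normalized channel features, self included), applies
#' the local feature-modelling function `phi` (two 1x1 convolutions with a
#' ReLU between), max-reduces over the neighbor axis, and sums the per-scale
#' outputs.
#'
#' @inheritParams mhsaBlock
#' @param scales integer vector of neighbor counts; `max(scales)` must not
#'   exceed the number of positions.
#' @return a C x P matrix.
#' @export
msmlp <- function(x, params, scales = params$scales) {
  nd_value(fw_msmlp(nd_const(token_matrix(x)), params, scales = scales))
}

#' Multi-scale attention block
#'
#' The full block: `X' = MHSA(LN(X)) + X`, then `MSMLP(LN(X')) + X'`.
#'
#' @inheritParams mhsaBlock
#' @return a C x P matrix with the shape of the input.
#' @export
multiScaleAttention <- function(x, params) {
  nd_value(fw_ms_attention(nd_const(token_matrix(x)), params))
}

#' Scaled dot-product attention
#'
#' `SoftMax(Q K^T / sqrt(D)) V` with tokens as rows. Each row of the softmax
#' matrix sums to one.
#'
#' @param Q n x D query matrix.
#' @param K m x D key matrix.
#' @param V m x Dv value matrix.
#' @return an n x Dv matrix; the attention weights are attached as attribute
#'   `"weights"`.
#' @export
scaledAttention <- function(Q, K, V) {
  stopifnot(ncol(Q) == ncol(K), nrow(K) == nrow(V))
  D <- ncol(Q)
  S <- Q %*% t(K) / sqrt(D)
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  A <- E / rowSums(E)
  out <- A %*% V
  attr(out, "weights") <- A
  out
}

#' Cluster token features with seeded k-means
#'
#' Groups L2-normalized token vectors into `clusters` clusters (by default 3,
#' targeting optic disc, optic cup and background token populations) using
#' k-means++ initialization and at most `iters` Lloyd iterations over the
#' full token mini-batch. Empty clusters are repaired by re-seeding their
#' centroid at the point farthest from its current centroid; identical
#' degenerate inputs therefore terminate with every token in the first
#' cluster.
#'
#' @param x a [TokenTensor-class] or C x P matrix.
#' @param clusters number of clusters (default 3).
#' @param seed optional integer seed making the assignment deterministic.
#' @param iters maximum Lloyd iterations (default 10).
#' @return a list of class `ClusterState`: `labels` (length-P integers in
#'   `1..clusters`), `centroids` (clusters x C matrix in normalized-feature
#'   space), `clusters`.
#' @export
clusterAssign <- function(x, clusters = 3L, seed = NULL, iters = 10L) {
  v <- token_matrix(x)
  P <- ncol(v)
  if (P < clusters)
    stop("number of positions (", P, ") is below the cluster count (",
         clusters, ")")
  n <- sqrt(colSums(v^2) + 1e-12)
  pts <- t(sweep(v, 2L, n, `/`))   # P x C points
  with_seed(seed, {
    centers <- matrix(0, clusters, ncol(pts))
    ci <- sample.int(P, 1L)
    centers[1L, ] <- pts[ci, ]
    d2 <- rowSums(sweep(pts, 2L, centers[1L, ])^2)
    if (clusters > 1L) for (j in 2:clusters) {
      ci <- if (sum(d2) <= 1e-12) sample.int(P, 1L)
            else sample.int(P, 1L, prob = d2)
      centers[j, ] <- pts[ci, ]
      d2 <- pmin(d2, rowSums(sweep(pts, 2L, centers[j, ])^2))
    }
    labels <- integer(P)
    for (it in seq_len(iters)) {
      DM <- outer(rowSums(pts^2), rowSums(centers^2), `+`) -
        2 * pts %*% t(centers)
      newlab <- max.col(-DM, ties.method = "first")
      empty <- which(tabulate(newlab, clusters) == 0L)
      if (length(empty) > 0L) {
        for (j in empty) {
          far <- which.max(DM[cbind(seq_len(P), newlab)])
          centers[j, ] <- pts[far, ]
        }
        DM <- outer(rowSums(pts^2), rowSums(centers^2), `+`) -
          2 * pts %*% t(centers)
        newlab <- max.col(-DM, ties.method = "first")
      }
      converged <- identical(newlab, labels)
      labels <- newlab
      for (j in seq_len(clusters)) {
        mem <- labels == j
        if (any(mem)) centers[j, ] <- colMeans(pts[mem, , drop = FALSE])
      }
      if (converged) break
    }
    structure(list(labels = labels, centroids = centers,
                   clusters = as.integer(clusters)),
              class = "ClusterState")
  })
}

#' @export
print.ClusterState <- function(x, ...) {
  cat(sprintf("ClusterState: %d clusters, sizes %s\n", x$clusters,
              paste(tabulate(x$labels, x$clusters), collapse = "/")))
  invisible(x)
}

#' Aggregation attention block
#'
#' Clusters the tokens into `clusters` groups, runs scaled dot-product
#' attention separately over the tokens of each group and over the centroid
#' sequence (shared Q/K/V projections, residual connections on both paths),
#' then broadcasts each updated centroid to its member positions and adds it
#' to the updated member tokens.
#'
#' @inheritParams clusterAssign
#' @param params parameters from [aggregationParams()].
#' @return a C x P matrix with the shape of the input.
#' @export
aggregationAttention <- function(x, params, clusters = 3L, seed = NULL) {
  nd_value(fw_aggregation(nd_const(token_matrix(x)), params,
                          clusters = clusters, seed = seed))
}
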