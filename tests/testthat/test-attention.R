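test_that("token flattening is a bijection with the documented layout", {
  set.seed(1)
  x <- array(rnorm(1 * 4 * 2 * 2), c(1, 4, 2, 2))
  tt <- flattenTokens(x)
  expect_s4_class(tt, "TokenTensor")
  expect_equal(ncol(tokenValues(tt)), 4L)
  expect_equal(unflattenTokens(tt), x)
  # p = n*h*w + r*w + c: with h = w = 1 and N = 2, positions follow groups
  x2 <- array(0, c(2, 3, 1, 1)); x2[1, , 1, 1] <- 1:3; x2[2, , 1, 1] <- 4:6
  tt2 <- flattenTokens(x2, groupSize = 2L)
  expect_equal(tokenValues(tt2), cbind(c(1, 2, 3), c(4, 5, 6)))
  # row-major within a map: (r, c) -> p = r*w + c
  x3 <- array(0, c(1, 1, 2, 3)); x3[1, 1, , ] <- matrix(1:6, 2, 3, byrow = TRUE)
  expect_equal(as.vector(tokenValues(flattenTokens(x3))), 1:6)
  # batched round trip
  xb <- array(rnorm(2 * 8 * 3 * 3), c(2, 8, 3, 3))
  expect_equal(unflattenTokens(flattenTokens(xb)), xb)
})

test_that("token similarity is the Gram matrix of normalized features", {
  x <- cbind(c(1, 2, 3), c(1, 2, 3))          # identical tokens
  expect_equal(tokenSimilarity(x), matrix(1, 2, 2))
  expect_equal(tokenSimilarity(diag(3)), diag(3))   # orthonormal set
  set.seed(2)
  x <- matrix(rnorm(4 * 5), 4, 5)
  S <- tokenSimilarity(x)
  expect_equal(S, oracle_similarity(x), tolerance = 1e-10)
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 5))
  expect_true(all(S >= -1 - 1e-12 & S <= 1 + 1e-12))
  expect_true(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) > -1e-5)
  x[, 3] <- 0
  expect_error(tokenSimilarity(x), "degenerate")
})

test_that("top-K neighbor selection matches the sort oracle, self included", {
  # identical tokens: all ties, selected in index order
  S <- matrix(1, 4, 4)
  nb <- topkNeighbors(S, 4)
  expect_true(all(apply(nb$indices, 1L, identical, 1:4)))
  # identity similarity, k = 1: each query selects itself
  expect_equal(as.vector(topkNeighbors(diag(5), 1)$indices), 1:5)
  set.seed(3)
  for (trial in 1:25) {
    x <- matrix(rnorm(3 * 7), 3, 7)
    S <- tokenSimilarity(x)
    k <- sample(1:7, 1)
    expect_equal(topkNeighbors(S, k)$indices,
                 matrix(oracle_topk(S, k), ncol = k))
  }
  # cosine diagonal is maximal, so the self index is always present
  expect_true(all(sapply(1:7, function(i) i %in% topkNeighbors(S, 3)$indices[i, ])))
  expect_error(topkNeighbors(S, 8), "exceeds")
})

test_that("scaled attention matches the loop oracle and its edge cases", {
  set.seed(4)
  V1 <- matrix(rnorm(3), 1, 3)
  out <- scaledAttention(matrix(rnorm(2), 1, 2), matrix(rnorm(2), 1, 2), V1)
  expect_equal(as.vector(out), as.vector(V1))        # softmax of a singleton
  K <- matrix(rep(c(1, -1), each = 4), 4, 2)         # identical keys
  V <- matrix(rnorm(12), 4, 3)
  out <- scaledAttention(matrix(rnorm(2), 1, 2), K, V)
  expect_equal(as.vector(out), colMeans(V))
  Q <- matrix(rnorm(16), 4, 4); K <- matrix(rnorm(16), 4, 4)
  V <- matrix(rnorm(16), 4, 4)
  got <- scaledAttention(Q, K, V)
  expect_equal(unclass(got), oracle_scaled_attention(Q, K, V),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(rowSums(attr(got, "weights")), rep(1, 4))
})

test_that("MHSA block has the residual-identity and single-token reductions", {
  set.seed(5)
  C <- 8L; P <- 6L
  x <- matrix(rnorm(C * P), C, P)
  p <- attentionParams(C, heads = 4L, seed = 1)
  # zero output projection (the default init) => exact identity
  expect_equal(mhsaBlock(x, p), x)
  # single token: softmax over one item is 1, so MHSA(LN(x)) is the value
  # projection of LN(x); expose it with an identity output projection
  p$Wo <- diag(C)
  x1 <- matrix(rnorm(C), C, 1)
  mu <- mean(x1); sd_ <- sqrt(mean((x1 - mu)^2) + 1e-5)
  xn <- (x1 - mu) / sd_
  expect_equal(mhsaBlock(x1, p), p$Wv %*% xn + p$bv + x1, tolerance = 1e-12)
})

test_that("single-head MHSA equals the explicit loop oracle", {
  set.seed(6)
  C <- 4L; P <- 5L
  x <- matrix(rnorm(C * P), C, P)
  p <- attentionParams(C, heads = 1L, seed = 2)
  p$Wo <- matrix(rnorm(C * C) * 0.3, C, C)
  expect_equal(mhsaBlock(x, p), oracle_mhsa1(x, p), tolerance = 1e-10)
})

test_that("msmlp matches the gather/phi/max/sum loop oracle", {
  set.seed(7)
  # identity phi, single scale k = 1, orthogonal non-negative tokens:
  # each token is its own sole neighbor and passes through unchanged
  C <- 4L
  p1 <- attentionParams(C, heads = 2L, scales = 1L, seed = 3)
  p1$phi[[1]]$W1 <- diag(C); p1$phi[[1]]$W2 <- diag(C)
  x <- diag(C) * 2
  expect_equal(msmlp(x, p1), x)
  # constant token field stays constant across positions
  p2 <- attentionParams(C, heads = 2L, scales = c(2L, 3L), seed = 4)
  for (s in seq_along(p2$phi)) p2$phi[[s]]$W2 <- matrix(rnorm(C * C) * 0.5, C, C)
  xc <- matrix(rep(c(1, -2, 0.5, 3), 6), C, 6)
  yc <- msmlp(xc, p2)
  expect_true(all(abs(yc - yc[, 1]) < 1e-12))
  # random instances against the loop oracle
  for (trial in 1:20) {
    P <- sample(4:8, 1)
    x <- matrix(rnorm(C * P), C, P)
    expect_equal(msmlp(x, p2), oracle_msmlp(x, p2, c(2L, 3L)), tolerance = 1e-8)
  }
  expect_error(msmlp(x, p2, scales = 50L), "exceeds")
})

test_that("multi-scale attention block reduces to identity at zero init and preserves shape", {
  set.seed(8)
  C <- 8L
  p <- attentionParams(C, heads = 4L, scales = c(2L, 3L), seed = 5)
  for (P in c(4L, 6L, 9L)) {
    x <- matrix(rnorm(C * P), C, P)
    expect_equal(multiScaleAttention(x, p), x)   # Wo = 0 and phi$W2 = 0
  }
})

test_that("gradients reach every parameter of both attention sub-blocks", {
  set.seed(9)
  C <- 4L; P <- 6L
  x <- matrix(rnorm(C * P), C, P)
  p0 <- attentionParams(C, heads = 2L, scales = c(2L, 3L), seed = 6)
  p0$Wo <- matrix(rnorm(C * C) * 0.3, C, C)
  for (s in seq_along(p0$phi)) p0$phi[[s]]$W2 <- matrix(rnorm(C * C) * 0.3, C, C)
  wrap <- function(obj) {
    if (is.list(obj)) lapply(obj, wrap)
    else if (is.numeric(obj) && length(obj) > 1L) odcseg:::nd_param(obj)
    else obj
  }
  pn <- wrap(p0)
  pn$heads <- p0$heads; pn$scales <- p0$scales
  loss <- odcseg:::nd_sum(odcseg:::nd_mul(
    odcseg:::fw_ms_attention(odcseg:::nd_const(x), pn),
    odcseg:::nd_const(matrix(rnorm(C * P), C, P))))
  odcseg:::nd_backward(loss)
  leaves <- list(pn$ln1_g, pn$ln1_b, pn$Wq, pn$bq, pn$Wk, pn$bk, pn$Wv, pn$bv,
                 pn$Wo, pn$bo, pn$ln2_g, pn$ln2_b,
                 pn$phi[[1]]$W1, pn$phi[[1]]$b1, pn$phi[[1]]$W2, pn$phi[[1]]$b2,
                 pn$phi[[2]]$W1, pn$phi[[2]]$b1, pn$phi[[2]]$W2, pn$phi[[2]]$b2)
  for (leaf in leaves) {
    expect_false(is.null(leaf$grad))
    expect_true(any(leaf$grad != 0))
  }
  # finite-difference spot check on one weight of the first phi
  w <- pn$phi[[1]]$W1
  h <- 1e-5
  maskm <- odcseg:::nd_value(loss$parents[[1]]$parents[[2]])
  f <- function(W1val) {
    p2 <- p0; p2$phi[[1]]$W1 <- W1val
    sum(odcseg:::nd_value(odcseg:::fw_ms_attention(odcseg:::nd_const(x), p2)) * maskm)
  }
  Wp <- p0$phi[[1]]$W1; Wm <- p0$phi[[1]]$W1
  Wp[2, 3] <- Wp[2, 3] + h; Wm[2, 3] <- Wm[2, 3] - h
  expect_equal(w$grad[2, 3], (f(Wp) - f(Wm)) / (2 * h), tolerance = 1e-3)
})

test_that("k-means clustering recovers separated groups and handles degeneracy", {
  set.seed(10)
  # three well-separated triplets in feature space
  base <- diag(3) * 5
  pts <- cbind(base[, 1] + rnorm(3, 0, .05), base[, 1] + rnorm(3, 0, .05),
               base[, 1] + rnorm(3, 0, .05),
               base[, 2] + rnorm(3, 0, .05), base[, 2] + rnorm(3, 0, .05),
               base[, 2] + rnorm(3, 0, .05),
               base[, 3] + rnorm(3, 0, .05), base[, 3] + rnorm(3, 0, .05),
               base[, 3] + rnorm(3, 0, .05))
  cs <- clusterAssign(pts, clusters = 3L, seed = 42)
  truth <- rep(1:3, each = 3)
  # exhaustive comparison up to label permutation
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  ok <- any(vapply(perms, function(pm) all(pm[cs$labels] == truth) ||
                     all(pm[truth] == cs$labels), logical(1)))
  expect_true(ok)
  # independent cross-check: same partition as stats::kmeans on these points
  ptsn <- t(pts) / sqrt(colSums(pts^2))
  km <- stats::kmeans(ptsn, centers = 3, nstart = 5)
  expect_equal(length(unique(paste(cs$labels, km$cluster))), 3L)
  # identical tokens collapse into the first cluster and still terminate
  xeq <- matrix(rep(c(1, 2, 1), 7), 3, 7)
  cse <- clusterAssign(xeq, clusters = 3L, seed = 1)
  expect_true(all(cse$labels == 1L))
  # determinism
  expect_identical(clusterAssign(pts, 3L, seed = 7)$labels,
                   clusterAssign(pts, 3L, seed = 7)$labels)
})

test_that("aggregation attention reduces to input + centroid under zero projections", {
  set.seed(11)
  C <- 4L; P <- 9L
  x <- matrix(rnorm(C * P), C, P)
  p <- aggregationParams(C, seed = 1)
  p$Wq[] <- 0; p$Wk[] <- 0; p$Wv[] <- 0
  out <- aggregationAttention(x, p, clusters = 1L, seed = 3)
  xn <- sweep(x, 2L, sqrt(colSums(x^2) + 1e-12), `/`)
  expect_equal(out, x + rowMeans(xn), tolerance = 1e-10)
})

test_that("aggregation attention is permutation-equivariant for a fixed assignment", {
  set.seed(12)
  C <- 4L; P <- 8L
  x <- matrix(rnorm(C * P), C, P)
  p <- aggregationParams(C, seed = 2)
  p$Wv <- matrix(rnorm(C * C) * 0.3, C, C)
  out <- aggregationAttention(x, p, clusters = 1L, seed = 5)
  perm <- sample(P)
  out_p <- aggregationAttention(x[, perm], p, clusters = 1L, seed = 5)
  expect_equal(out_p[, order(perm)], out, tolerance = 1e-10)
  # shape contract for arbitrary P
  for (P2 in c(5L, 13L)) {
    x2 <- matrix(rnorm(C * P2), C, P2)
    expect_equal(dim(aggregationAttention(x2, p, clusters = 3L, seed = 1)),
                 c(C, P2))
  }
})
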