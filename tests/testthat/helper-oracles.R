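# Independent brute-force oracles used by unit and acceptance tests.
# These are written with explicit loops and never call the package's own
# vectorized implementations.

oracle_similarity <- function(x) {
  P <- ncol(x)
  S <- matrix(0, P, P)
  for (i in seq_len(P)) for (j in seq_len(P)) {
    a <- x[, i] / sqrt(sum(x[, i]^2))
    b <- x[, j] / sqrt(sum(x[, j]^2))
    S[i, j] <- sum(a * b)
  }
  S
}

oracle_topk <- function(S, k) {
  t(apply(S, 1L, function(row) order(-row)[seq_len(k)]))
}

oracle_scaled_attention <- function(Q, K, V) {
  n <- nrow(Q); m <- nrow(K); D <- ncol(Q)
  out <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    s <- numeric(m)
    for (j in seq_len(m)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(D)
    a <- exp(s - max(s)); a <- a / sum(a)
    for (j in seq_len(m)) out[i, ] <- out[i, ] + a[j] * V[j, ]
  }
  out
}

# explicit gather/phi/max/sum oracle for the multi-scale KNN MLP
oracle_msmlp <- function(x, params, scales) {
  P <- ncol(x); C <- nrow(x)
  S <- oracle_similarity(x)
  out <- matrix(0, C, P)
  for (si in seq_along(scales)) {
    k <- scales[si]
    pp <- params$phi[[si]]
    for (i in seq_len(P)) {
      nb <- order(-S[i, ])[seq_len(k)]
      best <- rep(-Inf, C)
      for (j in nb) {
        h <- pmax(pp$W1 %*% x[, j] + pp$b1, 0)
        h <- pp$W2 %*% h + pp$b2
        best <- pmax(best, as.vector(h))
      }
      out[, i] <- out[, i] + best
    }
  }
  out
}

# loop-based single-head attention with pre-norm LayerNorm and residual,
# mirroring the mhsaBlock contract for heads = 1
oracle_mhsa1 <- function(x, p, eps = 1e-5) {
  C <- nrow(x); P <- ncol(x)
  xn <- x
  for (i in seq_len(P)) {
    mu <- mean(x[, i]); sd_ <- sqrt(mean((x[, i] - mu)^2) + eps)
    xn[, i] <- (x[, i] - mu) / sd_ * p$ln1_g + p$ln1_b
  }
  Q <- p$Wq %*% xn + p$bq; K <- p$Wk %*% xn + p$bk; V <- p$Wv %*% xn + p$bv
  out <- matrix(0, C, P)
  for (i in seq_len(P)) {
    s <- numeric(P)
    for (j in seq_len(P)) s[j] <- sum(Q[, i] * K[, j]) / sqrt(C)
    a <- exp(s - max(s)); a <- a / sum(a)
    for (j in seq_len(P)) out[, i] <- out[, i] + a[j] * V[, j]
  }
  p$Wo %*% out + p$bo + x
}

oracle_confusion <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && gt[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}
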