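# Training objectives: the rim-constrained multi-label segmentation loss and
# the InfoNCE contrastive loss. Node-level fw_* versions back the training
# loops; the exported functions evaluate on plain arrays.

# binary cross-entropy of probabilities p against binary g, probabilities
# clamped to [eps, 1-eps]; mean over elements; node-level
fw_bce <- function(p, g, eps = 1e-6) {
  p <- nd_clamp(p, eps, 1 - eps)
  g <- nd_value(as_node(g))
  term <- nd_add(nd_mul(nd_log(p), nd_const(g)),
                 nd_mul(nd_log(nd_sub(nd_const(array(1, dim(g))), p)),
                        nd_const(1 - g)))
  nd_scale(nd_mean(term), -1)
}

# rim-constrained multi-label loss on probability nodes
fw_rim_loss <- function(p_disc, p_cup, g_disc, g_cup, eps = 1e-6) {
  g_rim <- g_disc - g_cup
  ld <- fw_bce(p_disc, g_disc, eps)
  lc <- fw_bce(p_cup, g_cup, eps)
  lr <- fw_bce(nd_sub(p_disc, p_cup), g_rim, eps)
  nd_scale(nd_add(nd_add(ld, lc), lr), 1 / 3)
}

#' Rim-constrained multi-label segmentation loss
#'
#' Treats joint disc/cup segmentation as three binary classification
#' problems: disc vs background, cup vs background, and rim vs background,
#' where the rim ground truth is `g_disc - g_cup` and the rim "probability"
#' is the difference `p_disc - p_cup`, clamped to `[eps, 1-eps]` for
#' numerical safety (the network may predict cup mass outside the disc). The
#' three per-pixel binary cross-entropies are averaged over pixels and
#' combined as `(Loss_D + Loss_C + Loss_R) / 3`, returned as a positive
#' quantity to minimize (negative log-likelihood convention).
#'
#' @param pDisc,pCup numeric arrays of per-pixel probabilities in `[0, 1]`
#'   (any common shape), or a [MaskPair-class] passed as `pDisc`.
#' @param gDisc,gCup binary ground-truth arrays of the same shape; `gCup`
#'   must be contained in `gDisc`.
#' @param eps clamp constant (default `1e-6`).
#' @return scalar loss, with the three components attached as attribute
#'   `"components"` (named `disc`, `cup`, `rim`).
#' @examples
#' # single pixel: -(log 0.8 + log 0.7 + log 0.5)/3
#' rimLoss(0.8, 0.3, 1, 0)
#' @export
rimLoss <- function(pDisc, pCup = NULL, gDisc = NULL, gCup = NULL, eps = 1e-6) {
  if (is(pDisc, "MaskPair")) {
    mp <- pDisc
    if (is.null(gCup)) { gCup <- gDisc; gDisc <- pCup }
    pCup <- cupProb(mp); pDisc <- discProb(mp)
  }
  pDisc <- as.array(pDisc); pCup <- as.array(pCup)
  gDisc <- as.array(gDisc); gCup <- as.array(gCup)
  if (min(pDisc) < 0 || max(pDisc) > 1 || min(pCup) < 0 || max(pCup) > 1)
    stop("probabilities must lie in [0, 1]")
  if (!all(gDisc %in% c(0, 1)) || !all(gCup %in% c(0, 1)))
    stop("ground truths must be binary")
  if (any(gCup > gDisc))
    stop("invalid ground truth: cup pixels found outside the disc")
  bce <- function(p, g) {
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(g * log(p) + (1 - g) * log(1 - p))
  }
  ld <- bce(pDisc, gDisc)
  lc <- bce(pCup, gCup)
  lr <- bce(pDisc - pCup, gDisc - gCup)
  structure((ld + lc + lr) / 3,
            components = c(disc = ld, cup = lc, rim = lr))
}

#' InfoNCE contrastive loss
#'
#' `L = -log( exp(q.k+ / tau) / sum_i exp(q.k_i / tau) )` where the sum runs
#' over the one positive key and `K` negative keys. Finite for all unit-norm
#' inputs and any `tau > 0`; equals `log(K + 1)` when the positive and all
#' negatives have identical similarity to the query.
#'
#' @param q query embedding (unit-norm numeric vector).
#' @param kPos positive key (unit-norm vector of the same length).
#' @param kNeg matrix of negative keys, one per row (or a single vector).
#' @param tau temperature, `> 0` (default 0.07).
#' @return scalar loss.
#' @examples
#' e <- c(1, 0); infoNCE(e, e, matrix(c(0, 1), 1), tau = 1)  # log(1 + exp(-1))
#' @export
infoNCE <- function(q, kPos, kNeg, tau = 0.07) {
  if (tau <= 0) stop("tau must be positive")
  if (is.null(dim(kNeg))) kNeg <- matrix(kNeg, nrow = 1L)
  if (nrow(kNeg) < 1L) stop("at least one negative key is required")
  s <- c(sum(q * kPos), as.vector(kNeg %*% q)) / tau
  m <- max(s)
  -(s[1] - m - log(sum(exp(s - m))))
}

# symmetric in-batch (NT-Xent style) InfoNCE over 2B embeddings, node-level.
# E: d x 2B embedding matrix node (columns L2-normalized); columns 2i-1 and
# 2i are the two views of source i. Every other column in the batch serves
# as a negative, so K = 2*(B-1) ... with the partner excluded from the
# negatives the denominator runs over the partner plus the 2B-2 others.
fw_info_nce_batch <- function(E, tau = 0.07) {
  n <- ncol(nd_value(E))
  S <- nd_scale(nd_crossprod(E, E), 1 / tau)
  # exclude self-similarity from every denominator
  mask <- diag(n) * -1e9
  M <- nd_add(S, nd_const(mask))
  mx <- apply(nd_value(M), 1L, max)
  M <- nd_sub(M, nd_const(matrix(mx, n, n)))
  lse <- nd_log(nd_rowsums(nd_exp(M)))
  partner <- ifelse(seq_len(n) %% 2L == 1L, seq_len(n) + 1L, seq_len(n) - 1L)
  pos <- nd_gather_elems(M, cbind(seq_len(n), partner))
  nd_mean(nd_sub(lse, pos))
}
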