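test_that("rim loss reproduces hand-computed values and limits", {
  # single pixel, p_D = 0.8, p_C = 0.3, g_D = 1, g_C = 0 (g_R = 1)
  got <- rimLoss(0.8, 0.3, 1, 0)
  expect_equal(as.numeric(got), -(log(0.8) + log(0.7) + log(0.5)) / 3,
               tolerance = 1e-12)
  expect_equal(as.numeric(got), 0.4243, tolerance = 1e-3)
  comp <- attr(got, "components")
  expect_equal(unname(comp), c(-log(0.8), -log(0.7), -log(0.5)),
               tolerance = 1e-12)

  # perfect prediction: loss vanishes up to the clamp
  g <- matrix(c(1, 1, 0, 0, 1, 0), 2, 3)
  gc <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3)
  expect_lt(as.numeric(rimLoss(g, gc, g, gc)), 1e-5)

  # uniform 0.5 maps: Loss_D = Loss_C = log 2; Loss_R follows the clamped
  # closed form and stays finite
  eps <- 1e-6
  p <- matrix(0.5, 4, 4)
  gd <- matrix(0, 4, 4); gd[2:3, 2:3] <- 1
  gcup <- matrix(0, 4, 4); gcup[2, 2] <- 1
  out <- rimLoss(p, p, gd, gcup)
  comp <- attr(out, "components")
  expect_equal(unname(comp[c("disc", "cup")]), rep(log(2), 2), tolerance = 1e-12)
  grim <- gd - gcup
  expect_equal(unname(comp["rim"]),
               -mean(grim * log(eps) + (1 - grim) * log(1 - eps)),
               tolerance = 1e-9)
  expect_true(is.finite(as.numeric(out)))
})

test_that("rim loss validates its inputs", {
  expect_error(rimLoss(0.5, 0.5, 0, 1), "outside the disc")
  expect_error(rimLoss(1.5, 0.5, 1, 0), "probabilities")
  expect_error(rimLoss(0.5, 0.5, 0.7, 0), "binary")
})

test_that("rim loss is non-negative and reduces to standard BCEs without a cup", {
  set.seed(21)
  eps <- 1e-6
  for (trial in 1:20) {
    pd <- matrix(runif(25), 5, 5)
    pc <- pd * matrix(runif(25), 5, 5)      # keep p_C <= p_D
    gd <- matrix(rbinom(25, 1, 0.4), 5, 5)
    gcv <- gd * matrix(rbinom(25, 1, 0.4), 5, 5)
    expect_gte(as.numeric(rimLoss(pd, pc, gd, gcv)), 0)
  }
  # cup-free reduction: g_C = 0 and p_C = eps makes Loss_C ~ 0 and
  # Loss_R ~ Loss_D, so the total is the mean of three standard BCEs
  pd <- matrix(runif(25, 0.05, 0.95), 5, 5)
  gd <- matrix(rbinom(25, 1, 0.5), 5, 5)
  pc <- matrix(eps, 5, 5)
  bce <- function(p, g) -mean(g * log(p) + (1 - g) * log(1 - p))
  expected <- (bce(pd, gd) + bce(matrix(1 - eps, 5, 5), 1 - 0 * gd) * 0 +
                 bce(pmin(pmax(pd - eps, eps), 1 - eps), gd)) / 3
  expect_equal(as.numeric(rimLoss(pd, pc, gd, 0 * gd)),
               expected, tolerance = 1e-4)
})

test_that("InfoNCE reproduces closed forms and is monotone in the positive", {
  # uniform similarities: L = log(K + 1); K = 14 -> log 15
  q <- c(1, 0, 0)
  kpos <- c(0, 1, 0)
  kneg <- matrix(rep(c(0, 0, 1), 14), 14, 3, byrow = TRUE)
  kneg_rot <- t(apply(kneg, 1, function(r) c(0, 1, 0)))  # same dot as positive
  expect_equal(infoNCE(q, kpos, kneg_rot, tau = 0.07), log(15), tolerance = 1e-6)
  expect_equal(infoNCE(q, kpos, kneg_rot, tau = 1.3), log(15), tolerance = 1e-6)
  expect_equal(log(15), 2.708, tolerance = 1e-3)

  # one negative with q.k = 0 and q.k+ = 1 at tau = 1
  expect_equal(infoNCE(c(1, 0), c(1, 0), matrix(c(0, 1), 1), tau = 1),
               log(1 + exp(-1)), tolerance = 1e-12)
  expect_equal(log(1 + exp(-1)), 0.3133, tolerance = 1e-3)

  # increasing the positive similarity strictly decreases the loss
  set.seed(22)
  kneg <- matrix(rnorm(10), 5, 2)
  kneg <- kneg / sqrt(rowSums(kneg^2))
  angles <- seq(1.2, 0, length.out = 8)
  q0 <- c(1, 0)
  losses <- vapply(angles, function(a) {
    infoNCE(q0, c(cos(a), sin(a)), kneg, tau = 0.2)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(infoNCE(q0, q0, kneg, tau = 0), "positive")
})

test_that("InfoNCE matches brute-force softmax cross-entropy on random batches", {
  set.seed(23)
  for (trial in 1:100) {
    d <- sample(3:6, 1)
    K <- sample(1:8, 1)
    unit <- function(v) v / sqrt(sum(v^2))
    q <- unit(rnorm(d)); kp <- unit(rnorm(d))
    kn <- t(apply(matrix(rnorm(K * d), K, d), 1, unit))
    tau <- runif(1, 0.05, 1)
    # oracle: softmax cross-entropy with the positive as class 1
    logits <- c(sum(q * kp), kn %*% q) / tau
    p <- exp(logits - max(logits)); p <- p / sum(p)
    expect_equal(infoNCE(q, kp, kn, tau), -log(p[1]), tolerance = 1e-6)
  }
})

test_that("batched in-batch InfoNCE agrees with the per-anchor definition", {
  set.seed(24)
  d <- 6L; B <- 4L
  E <- matrix(rnorm(d * 2 * B), d, 2 * B)
  E <- sweep(E, 2L, sqrt(colSums(E^2)), `/`)
  tau <- 0.07
  node <- odcseg:::fw_info_nce_batch(odcseg:::nd_const(E), tau = tau)
  # per-anchor: positive is the partner, negatives are the 2B-2 other views
  per <- vapply(seq_len(2 * B), function(i) {
    partner <- if (i %% 2 == 1) i + 1 else i - 1
    negs <- setdiff(seq_len(2 * B), c(i, partner))
    infoNCE(E[, i], E[, partner], t(E[, negs]), tau = tau)
  }, numeric(1))
  expect_equal(odcseg:::nd_value(node), mean(per), tolerance = 1e-8)
})

test_that("both losses are differentiable with finite-difference agreement", {
  set.seed(25)
  # rim loss at 5 random interior points
  for (trial in 1:5) {
    pd <- matrix(runif(9, 0.2, 0.9), 3, 3)
    pc <- pd * matrix(runif(9, 0.1, 0.8), 3, 3)
    gd <- matrix(rbinom(9, 1, 0.5), 3, 3)
    gcv <- gd * matrix(rbinom(9, 1, 0.5), 3, 3)
    check_grads(function(p) {
      odcseg:::fw_rim_loss(p[[1]], p[[2]], gd, gcv)
    }, list(pd, pc), tol = 1e-3)
  }
  # batched InfoNCE wrt the (pre-normalization) embeddings
  E <- matrix(rnorm(4 * 6), 4, 6)
  check_grads(function(p) {
    En <- odcseg:::nd_l2norm_cols(p[[1]])
    odcseg:::fw_info_nce_batch(En, tau = 0.3)
  }, list(E), tol = 1e-3)
})
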