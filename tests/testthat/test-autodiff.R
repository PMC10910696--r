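test_that("elementwise and linear-algebra ops match central differences", {
  set.seed(11)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(20), 4, 5)
  b <- rnorm(3)

  check_grads(function(p) odcseg:::nd_sum(odcseg:::nd_mm(p[[1]], p[[2]])),
              list(A, B))
  check_grads(function(p) {
    y <- odcseg:::nd_add(odcseg:::nd_mm(p[[1]], p[[2]]), p[[3]])
    odcseg:::nd_mean(odcseg:::nd_relu(y))
  }, list(A, B, b))
  check_grads(function(p) {
    odcseg:::nd_sum(odcseg:::nd_mul(odcseg:::nd_sigmoid(p[[1]]),
                                    odcseg:::nd_t(odcseg:::nd_t(p[[1]]))))
  }, list(A))
  check_grads(function(p) {
    odcseg:::nd_sum(odcseg:::nd_log(odcseg:::nd_clamp(odcseg:::nd_sigmoid(p[[1]]),
                                                      1e-6, 1 - 1e-6)))
  }, list(A))
})

test_that("softmax, gather, reduction and norm ops match central differences", {
  set.seed(12)
  S <- matrix(rnorm(16), 4, 4)
  X <- matrix(rnorm(24), 4, 6)
  gam <- runif(4, 0.5, 1.5)
  bet <- rnorm(4)

  check_grads(function(p) {
    A <- odcseg:::nd_softmax_rows(p[[1]])
    odcseg:::nd_sum(odcseg:::nd_mul(A, A))
  }, list(S))
  check_grads(function(p) {
    g <- odcseg:::nd_gather_cols(p[[1]], c(1L, 3L, 3L, 5L))
    odcseg:::nd_mean(odcseg:::nd_mul(g, g))
  }, list(X))
  check_grads(function(p) {
    odcseg:::nd_sum(odcseg:::nd_gather_elems(p[[1]], cbind(1:4, c(2L, 1L, 4L, 3L))))
  }, list(S))
  check_grads(function(p) {
    odcseg:::nd_sum(odcseg:::nd_mul(odcseg:::nd_rowsums(p[[1]]),
                                    odcseg:::nd_const(c(1, -2, 3, 0.5))))
  }, list(X))
  check_grads(function(p) {
    y <- odcseg:::nd_layernorm_cols(p[[1]], p[[2]], p[[3]])
    odcseg:::nd_sum(odcseg:::nd_mul(y, y))
  }, list(X, gam, bet), tol = 1e-3)
  check_grads(function(p) {
    y <- odcseg:::nd_groupnorm(p[[1]], p[[2]], p[[3]], groups = 2L)
    odcseg:::nd_sum(odcseg:::nd_mul(y, y))
  }, list(X, gam, bet), tol = 1e-3)
  check_grads(function(p) {
    y <- odcseg:::nd_l2norm_cols(p[[1]])
    odcseg:::nd_sum(odcseg:::nd_mul(y, odcseg:::nd_const(matrix(1:24, 4, 6))))
  }, list(X), tol = 1e-3)
})

test_that("structural ops (rbind, rows, reshape, group-max) backpropagate", {
  set.seed(13)
  A <- matrix(rnorm(8), 2, 4)
  B <- matrix(rnorm(12), 3, 4)

  check_grads(function(p) {
    y <- odcseg:::nd_rbind(list(p[[1]], p[[2]]))
    odcseg:::nd_sum(odcseg:::nd_mul(y, y))
  }, list(A, B))
  check_grads(function(p) {
    odcseg:::nd_sum(odcseg:::nd_rows(p[[2]], 2:3))
  }, list(A, B))
  check_grads(function(p) {
    y <- odcseg:::nd_reshape(p[[1]], c(4, 2))
    odcseg:::nd_sum(odcseg:::nd_mul(y, y))
  }, list(A))
  X <- matrix(rnorm(3 * 12), 3, 12)   # P = 4 groups of K = 3
  check_grads(function(p) {
    odcseg:::nd_sum(odcseg:::nd_max_groupcols(p[[1]], 3L))
  }, list(X))
})

test_that("group-max takes the first member on ties and the max otherwise", {
  x <- matrix(c(1, 5, 5, 2,   3, 3, 1, 0), nrow = 1)  # two groups, K = 4
  y <- odcseg:::nd_max_groupcols(odcseg:::nd_const(x), 4L)
  expect_equal(as.vector(odcseg:::nd_value(y)), c(5, 3))
  p <- odcseg:::nd_param(x)
  odcseg:::nd_backward(odcseg:::nd_sum(odcseg:::nd_max_groupcols(p, 4L)))
  expect_equal(as.vector(p$grad), c(0, 1, 0, 0, 1, 0, 0, 0))
})

test_that("conv2d matches a direct dense convolution and its gradients", {
  set.seed(14)
  h <- 5L; w <- 6L; Cin <- 2L; Cout <- 3L; k <- 3L
  x <- matrix(rnorm(Cin * h * w), Cin, h * w)
  wt <- matrix(rnorm(Cout * Cin * k * k), Cout, Cin * k * k) * 0.5
  b <- rnorm(Cout)

  # brute-force convolution oracle (stride 1, pad 1), row-major positions
  conv_oracle <- function(x, wt, b, h, w, k, stride, pad) {
    Cin <- nrow(x); Cout <- nrow(wt)
    ho <- (h + 2 * pad - k) %/% stride + 1
    wo <- (w + 2 * pad - k) %/% stride + 1
    out <- matrix(0, Cout, ho * wo)
    for (ro in 0:(ho - 1)) for (co in 0:(wo - 1)) {
      acc <- b
      j <- 0
      for (kr in 0:(k - 1)) for (kc in 0:(k - 1)) {
        j <- j + 1
        ri <- ro * stride - pad + kr
        ci <- co * stride - pad + kc
        if (ri >= 0 && ri < h && ci >= 0 && ci < w) {
          px <- x[, ri * w + ci + 1]
          W <- wt[, ((j - 1) * Cin + 1):(j * Cin), drop = FALSE]
          acc <- acc + as.vector(W %*% px)
        }
      }
      out[, ro * wo + co + 1] <- acc
    }
    out
  }

  for (stride in c(1L, 2L)) {
    y <- odcseg:::nd_conv2d(odcseg:::nd_const(x), odcseg:::nd_const(wt),
                            odcseg:::nd_const(b), h, w, stride = stride)
    expect_equal(odcseg:::nd_value(y),
                 conv_oracle(x, wt, b, h, w, k, stride, 1L), tolerance = 1e-10)
  }
  check_grads(function(p) {
    y <- odcseg:::nd_conv2d(p[[1]], p[[2]], p[[3]], h, w, stride = 2L)
    odcseg:::nd_sum(odcseg:::nd_mul(y, y))
  }, list(x, wt, b), tol = 1e-3)
})

test_that("bilinear upsampling is exact on constants/linear ramps and differentiable", {
  h <- 4L; w <- 3L; C <- 2L
  const_map <- matrix(7, C, h * w)
  y <- odcseg:::nd_upsample2x(odcseg:::nd_const(const_map), h, w)
  expect_equal(dim(odcseg:::nd_value(y)), c(C, 4L * h * w))
  expect_true(all(abs(odcseg:::nd_value(y) - 7) < 1e-12))

  set.seed(15)
  x <- matrix(rnorm(C * h * w), C, h * w)
  check_grads(function(p) {
    y <- odcseg:::nd_upsample2x(p[[1]], h, w)
    odcseg:::nd_sum(odcseg:::nd_mul(y, y))
  }, list(x), tol = 1e-3)
})

test_that("RoiAlign pooling preserves constants and fixes the output size", {
  for (h in c(4L, 8L)) {
    x <- matrix(3.5, 2, h * h)
    y <- odcseg:::nd_roialign(odcseg:::nd_const(x), h, h, out = 24L)
    expect_equal(dim(odcseg:::nd_value(y)), c(2L, 576L))
    expect_true(all(abs(odcseg:::nd_value(y) - 3.5) < 1e-9))
  }
  set.seed(16)
  x <- matrix(rnorm(2 * 16), 2, 16)
  check_grads(function(p) {
    y <- odcseg:::nd_roialign(p[[1]], 4L, 4L, out = 6L)
    odcseg:::nd_sum(odcseg:::nd_mul(y, y))
  }, list(x), tol = 1e-3)
})

test_that("gradients accumulate across shared parameter reuse", {
  set.seed(17)
  x <- matrix(rnorm(6), 2, 3)
  p <- odcseg:::nd_param(x)
  y1 <- odcseg:::nd_sum(p)
  y2 <- odcseg:::nd_sum(odcseg:::nd_mul(p, p))
  loss <- odcseg:::nd_add(y1, y2)
  odcseg:::nd_backward(loss)
  expect_equal(p$grad, matrix(1, 2, 3) + 2 * x)
})
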