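# Central-difference gradient checker for the autodiff engine.
# f: function taking a list of plain arrays, returning a scalar ad_node
# built on nd_param-wrapped copies of those arrays.
num_grad <- function(fn, xs, wrt, h = 1e-5) {
  x <- xs[[wrt]]
  g <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  for (i in seq_along(x)) {
    xp <- xs; xp[[wrt]][i] <- x[i] + h
    xm <- xs; xm[[wrt]][i] <- x[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

check_grads <- function(build, xs, tol = 1e-4) {
  # build: function(list of ad_node params) -> scalar node
  ps <- lapply(xs, odcseg:::nd_param)
  loss <- build(ps)
  odcseg:::nd_backward(loss)
  fn <- function(vals) {
    odcseg:::nd_value(build(lapply(vals, odcseg:::nd_const)))
  }
  for (w in seq_along(xs)) {
    got <- ps[[w]]$grad
    if (is.null(got)) got <- array(0, dim = if (is.null(dim(xs[[w]]))) length(xs[[w]]) else dim(xs[[w]]))
    want <- num_grad(fn, xs, w)
    expect_equal(as.vector(got), as.vector(want), tolerance = tol,
                 info = paste("param", w))
  }
  invisible(odcseg:::nd_value(loss))
}
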