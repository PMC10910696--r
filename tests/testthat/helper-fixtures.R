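# shared fixtures: a direct ellipse rasterizer independent of the generator's
# internal helper (same pixel-center convention, written from the equation)
ellipse_mask_helper <- function(size, center, axes, rotation = 0) {
  m <- matrix(0, size, size)
  th <- rotation * pi / 180
  for (r in 0:(size - 1)) for (cc in 0:(size - 1)) {
    dr <- r - center[1]; dc <- cc - center[2]
    u <- cos(th) * dr + sin(th) * dc
    v <- -sin(th) * dr + cos(th) * dc
    if ((u / axes[1])^2 + (v / axes[2])^2 <= 1) m[r + 1, cc + 1] <- 1
  }
  m
}

# a tiny network configuration shared across unit tests (smaller than the
# shallow preset so shape/determinism/serialization tests stay fast)
tiny_config <- function(...) {
  segNetConfig(widths = c(8L, 16L, 32L, 64L), heads = 2L, ...)
}
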