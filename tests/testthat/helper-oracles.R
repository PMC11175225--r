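# Shared fixtures and independent oracles for the test suite.

# Naive direct convolution (nested loops) — the reference implementation the
# fast im2col path is checked against.
naive_conv2d <- function(x, w, b, stride = 1, pad = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; Co <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  out <- array(0, c(Ho, Wo, Co, N))
  for (n in seq_len(N)) for (co in seq_len(Co)) for (ho in seq_len(Ho))
    for (wo in seq_len(Wo)) {
      s <- b[co]
      for (c in seq_len(C)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
        hi <- (ho - 1) * stride - pad + kh
        wi <- (wo - 1) * stride - pad + kw
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          s <- s + x[hi, wi, c, n] * w[kh, kw, c, co]
      }
      out[ho, wo, co, n] <- s
    }
  out
}

# Central finite difference of fn (returning a scalar) at selected entries of
# a tensor's value.
numeric_grad <- function(fn, tensor, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    old <- tensor$value[i]
    tensor$value[i] <- old + eps
    up <- fn()
    tensor$value[i] <- old - eps
    dn <- fn()
    tensor$value[i] <- old
    (up - dn) / (2 * eps)
  }, numeric(1))
}

# A reduced generator specification used throughout the unit tests.
tiny_spec <- function(...) {
  generator_spec(num_blocks = 2L, convs_per_block = 3L, growth = 8L,
                 base_channels = 16L, fusion_width = 16L,
                 cbam_reduction = 4L, ...)
}

random_image <- function(h = 12, w = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raster_image(array(runif(h * w * 3), dim = c(h, w, 3)))
}

# small deterministic asymmetric patch (no symmetry under any dihedral code)
asym_patch <- function(n = 8) {
  v <- array(seq_len(n * n * 3) / (n * n * 3), dim = c(n, n, 3))
  raster_image(v)
}
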