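# Independent oracles and shared fixtures for the test suite.

# Direct O(n^2) zero-padded 1-D Gaussian convolution, written independently
# of the package's separable implementation.
conv1d_oracle <- function(x, fwhm_mm, voxel_mm, trunc = 4) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(trunc * sigma))
  k <- exp(-(( -r:r )^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in -r:r) {
      ij <- i + j
      if (ij >= 1 && ij <= n) acc <- acc + x[ij] * k[j + r + 1]
    }
    out[i] <- acc
  }
  out
}

# Dense n x n convolution matrix for the same kernel (for matrix-form
# PVC oracles).
dense_conv_matrix <- function(n, fwhm_mm, voxel_mm, trunc = 4) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(trunc * sigma))
  k <- exp(-(( -r:r )^2) / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) <= r) M[i, j] <- k[i - j + r + 1]
  }
  M
}

# Pseudo-1-D slab phantom: tissue pattern varies along x only; uniform in
# y, z so the 3-D code on the central line must match the 1-D oracle.
# Layout (x, in voxels): background | GM slab | WM slab | background.
make_slab <- function(n = 64, bg = 14, gm_vox = 6, wm_vox = 20) {
  gm1 <- wm1 <- numeric(n)
  gm1[(bg + 1):(bg + gm_vox)] <- 1
  wm1[(bg + gm_vox + 1):(bg + gm_vox + wm_vox)] <- 1
  gm <- array(rep(gm1, times = n * n), c(n, n, n))
  wm <- array(rep(wm1, times = n * n), c(n, n, n))
  list(gm = gm, wm = wm, gm1 = gm1, wm1 = wm1,
       gm_idx = (bg + 1):(bg + gm_vox), n = n)
}

# Deterministic phantom spec: no noise, no random field, no biological
# variability — every volume is a pure function of the burden.
nf_spec <- function(grid = c(48L, 48L, 48L), ...) {
  phantom_spec(grid_shape = grid, noise_sd = 0, field_sd = 0,
               sd_gm_ns = 0, sd_wm = 0, sd_spec = 0, ...)
}

# Cache expensive phantom builds across test files (shared session).
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}
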