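# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Gaussian smoothing of a 3D array by FFT (circular boundary), sigma in voxels.
gaussian_smooth3d <- function(x, sigma_vox) {
  d <- dim(x)
  axdist <- function(n) {
    i <- seq_len(n) - 1L
    pmin(i, n - i)
  }
  kx <- exp(-axdist(d[1])^2 / (2 * sigma_vox^2))
  ky <- exp(-axdist(d[2])^2 / (2 * sigma_vox^2))
  kz <- exp(-axdist(d[3])^2 / (2 * sigma_vox^2))
  kern <- outer(outer(kx, ky), kz)
  dim(kern) <- d
  kern <- kern / sum(kern)
  Re(fft(fft(x) * fft(kern), inverse = TRUE)) / length(x)
}
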