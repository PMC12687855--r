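# Exact DFT evaluation along radial spokes.  Samples on one spoke are
# equally spaced in k, so the per-sample phase factors follow a geometric
# recurrence and no per-sample exp() evaluation over the pixel grid is
# needed.  Used by the data simulator (forward) and for the Toeplitz PSF
# kernel of the nonlinear inversion (adjoint); the gridding reconstruction
# path shares no code with this.

pixel_grid <- function(n) seq_len(n) - 1 - floor(n / 2)

# phase matrix rows for one spoke: A[j, p] = exp(sgn * 2i*pi * (kx_j*X_p + ky_j*Y_p) / N)
spoke_phase_rows <- function(kx, ky, N, out, sgn) {
  xs <- pixel_grid(out)
  X <- rep(xs, times = out)
  Y <- rep(xs, each = out)
  m <- length(kx)
  A <- matrix(0 + 0i, m, out * out)
  dkx <- diff(kx); dky <- diff(ky)
  uniform <- m > 1 &&
    max(abs(dkx - dkx[1])) < 1e-9 && max(abs(dky - dky[1])) < 1e-9
  if (uniform) {
    row <- exp(sgn * 2i * pi * (kx[1] * X + ky[1] * Y) / N)
    step <- exp(sgn * 2i * pi * (dkx[1] * X + dky[1] * Y) / N)
    for (j in seq_len(m)) {
      A[j, ] <- row
      if (j < m) row <- row * step
    }
  } else {
    for (j in seq_len(m))
      A[j, ] <- exp(sgn * 2i * pi * (kx[j] * X + ky[j] * Y) / N)
  }
  A
}

# Forward DFT of images at radial sample positions.
# img: N^2 x C matrix (column-major pixels); kx, ky: nread x nspokes.
# Returns nread x nspokes x C array.
radial_dft_forward <- function(img, kx, ky, N) {
  stopifnot(nrow(img) == N * N)
  nread <- nrow(kx); nsp <- ncol(kx); C <- ncol(img)
  out <- array(0 + 0i, dim = c(nread, nsp, C))
  for (s in seq_len(nsp)) {
    A <- spoke_phase_rows(kx[, s], ky[, s], N, N, sgn = -1)
    out[, s, ] <- A %*% img
  }
  out
}

# Adjoint: images(p) = sum_j data_j * exp(+2i*pi*(k_j . x_p)/N) on an
# out x out centered pixel grid (phases still relative to N).
radial_dft_adjoint <- function(data, kx, ky, N, out = N) {
  nread <- nrow(kx); nsp <- ncol(kx)
  data <- array(data, dim = c(nread, nsp, length(data) / (nread * nsp)))
  C <- dim(data)[3]
  acc <- matrix(0 + 0i, out * out, C)
  for (s in seq_len(nsp)) {
    A <- spoke_phase_rows(kx[, s], ky[, s], N, out, sgn = +1)
    acc <- acc + crossprod(A, matrix(data[, s, ], nread, C))
  }
  array(acc, dim = c(out, out, C))
}
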