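# Per-frame reconstruction operators: Ram-Lak density compensation, adjoint
# NUFFT (gridding), root-sum-of-squares coil combination, centered resize.

#' Trajectory accessors
#'
#' Trajectories are stored as arrays of shape `(3, read, spoke[, frame])`
#' holding k-space coordinates in grid units (the sampled band spans
#' `+/- matrix/2`; the third coordinate is zero-padded for 2D).
#'
#' @param trj trajectory array.
#' @param frame 1-based frame index (for 4-d trajectories).
#' @return `traj_coords()`: list with real matrices `kx`, `ky` of shape
#'   `(read, spoke)`; `traj_angles()`: the spoke angles in `[0, pi)`;
#'   `traj_dirs()`: unit readout direction vectors, one column per spoke.
#' @export
traj_coords <- function(trj, frame = 1) {
  d <- dim(trj)
  if (length(d) == 3) d <- c(d, 1L)
  t4 <- array(trj, dim = d)
  list(kx = matrix(Re(t4[1, , , frame]), d[2], d[3]),
       ky = matrix(Re(t4[2, , , frame]), d[2], d[3]))
}

#' @rdname traj_coords
#' @export
traj_dirs <- function(trj, frame = 1) {
  co <- traj_coords(trj, frame)
  nr <- nrow(co$kx)
  dx <- co$kx[nr, ] - co$kx[1, ]
  dy <- co$ky[nr, ] - co$ky[1, ]
  len <- sqrt(dx^2 + dy^2)
  rbind(dx / len, dy / len)
}

#' @rdname traj_coords
#' @export
traj_angles <- function(trj, frame = 1) {
  dirs <- traj_dirs(trj, frame)
  (atan2(dirs[2, ], dirs[1, ])) %% pi
}

#' Ram-Lak filter for radial k-space data
#'
#' Multiplies every sample by a weight proportional to its k-space radius,
#' compensating the `1/|k|` sampling density of radial acquisition.  The
#' center sample (radius 0) gets the small nonzero weight `dk/8`, where `dk`
#' is the radial sample spacing, so the DC component contributes without
#' dominating.
#'
#' @param ksp complex array `(read, spoke, coil)` of one frame.
#' @param trj trajectory for the same frame, see [traj_coords()].
#' @param frame frame index within `trj`.
#' @return weighted k-space of the same shape.
#' @export
ramlak_filter <- function(ksp, trj, frame = 1) {
  co <- traj_coords(trj, frame)
  d <- dim(ksp)
  if (is.null(d)) d <- length(ksp)
  if (d[1] != nrow(co$kx) || d[2] != ncol(co$kx))
    stop("shape mismatch between k-space (", d[1], "x", d[2],
         ") and trajectory (", nrow(co$kx), "x", ncol(co$kx), ")")
  r <- sqrt(co$kx^2 + co$ky^2)
  dk <- stats::median(abs(diff(r[, 1])))
  w <- pmax(r, dk / 8)  # linear ramp with a small nonzero floor at DC
  ncoil <- prod(d) / (d[1] * d[2])
  array(as.vector(ksp) * rep(as.vector(w), ncoil), dim = d)
}

# --- Kaiser-Bessel gridding -------------------------------------------------

kb_beta <- function(width, os) pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)

kb_kernel <- function(u, width, beta) {
  t <- 2 * u / width
  out <- numeric(length(u))
  ok <- abs(t) <= 1
  out[ok] <- besselI(beta * sqrt(1 - t[ok]^2), 0)
  out
}

# Fourier transform of the Kaiser-Bessel window (per dimension), evaluated at
# normalized image coordinate xi = x / G.
kb_apod <- function(xi, width, beta) {
  g2 <- beta^2 - (pi * width * xi)^2
  out <- numeric(length(xi))
  pos <- g2 > 0
  out[pos] <- sinh(sqrt(g2[pos])) / sqrt(g2[pos])
  gn <- sqrt(-g2[!pos])
  out[!pos] <- ifelse(gn < 1e-12, 1, sin(gn) / gn)
  width * out
}

# Sparse spreading matrix (G^2 x M) for samples at (kx, ky) in grid units.
build_spread_matrix <- function(kx, ky, N, os = 1.5, width = 4) {
  G <- 2L * as.integer(ceiling(N * os / 2))
  beta <- kb_beta(width, os)
  kmax <- max(abs(c(kx, ky)))
  # one grid cell of slack so delay-corrected trajectories stay gridable
  if (kmax > N / 2 + 1)
    stop("trajectory sample at |k| = ", round(kmax, 3),
         " outside the band +/- ", N / 2)
  M <- length(kx)
  px <- kx * os + G / 2
  py <- ky * os + G / 2
  taps <- seq_len(width) - 1L  # j = ceiling(p - width/2) + 0..width-1
  jx <- outer(ceiling(px - width / 2), taps, `+`)
  jy <- outer(ceiling(py - width / 2), taps, `+`)
  wx <- kb_kernel(jx - px, width, beta)
  wy <- kb_kernel(jy - py, width, beta)
  dim(wx) <- dim(jx); dim(wy) <- dim(jy)
  # all width^2 combinations per sample
  ii <- rep(seq_len(M), times = width * width)
  tx <- rep(rep(seq_len(width), each = M), times = width)
  ty <- rep(seq_len(width), each = M * width)
  gx <- jx[cbind(ii, tx)] %% G
  gy <- jy[cbind(ii, ty)] %% G
  vals <- wx[cbind(ii, tx)] * wy[cbind(ii, ty)]
  Matrix::sparseMatrix(i = gy * G + gx + 1, j = ii, x = vals,
                       dims = c(G * G, M))
}

cifft_unnorm <- function(x) {
  fftshift(stats::fft(fftshift(x, inverse = TRUE), inverse = TRUE))
}

#' Adjoint NUFFT (gridding) of radial k-space data
#'
#' Interpolates the samples onto an oversampled Cartesian grid with a
#' Kaiser-Bessel kernel (width 4 grid cells, grid oversampling 1.5),
#' applies a centered inverse FFT, divides by the kernel's analytic
#' transform (apodization correction) and crops to the requested matrix.
#' The result agrees with the exact adjoint of non-uniform Fourier
#' sampling, `rho(x) = sum_j y_j exp(+2i pi k_j.x / N)`.
#'
#' @param ksp complex array `(read, spoke, coil)`.
#' @param trj trajectory, see [traj_coords()].
#' @param grid output matrix size `N` (band `+/- N/2`).
#' @param frame frame index within `trj`.
#' @param os grid oversampling factor.
#' @param width kernel width in grid cells.
#' @return complex coil images `(grid, grid, coil)`.
#' @export
nufft_adjoint <- function(ksp, trj, grid, frame = 1, os = 1.5, width = 4) {
  if (grid < 2) stop("grid size must be >= 2")
  co <- traj_coords(trj, frame)
  d <- dim(ksp)
  if (is.null(d)) d <- length(ksp)
  ncoil <- as.integer(prod(d) / (d[1] * d[2]))
  A <- build_spread_matrix(as.vector(co$kx), as.vector(co$ky), grid,
                           os = os, width = width)
  G <- as.integer(sqrt(nrow(A)))
  beta <- kb_beta(width, os)
  xi <- pixel_grid(G) / G
  apod <- outer(kb_apod(xi, width, beta), kb_apod(xi, width, beta))
  y <- matrix(as.vector(ksp), d[1] * d[2], ncoil)
  # sparse matrices are real-valued; apply to Re and Im separately
  g <- as.matrix(A %*% Re(y)) + 1i * as.matrix(A %*% Im(y))
  out <- array(0 + 0i, dim = c(grid, grid, ncoil))
  keep <- floor((G - grid) / 2) + seq_len(grid)
  for (cc in seq_len(ncoil)) {
    im <- cifft_unnorm(array(g[, cc], dim = c(G, G))) / apod
    out[, , cc] <- im[keep, keep]
  }
  out
}

#' Root-sum-of-squares coil combination
#'
#' @param x complex array whose given axis indexes coils.
#' @param coil_axis 0-based coil axis (default 2).
#' @return nonnegative real array with the coil axis collapsed to extent 1.
#' @export
rss_combine <- function(x, coil_axis = 2) {
  d <- md_dims(x)
  if (d[coil_axis + 1L] < 1) stop("coil axis has extent 0")
  out <- sqrt(apply(abs(x)^2, setdiff(seq_along(dim(x)), coil_axis + 1L), sum))
  newd <- dim(x)
  newd[coil_axis + 1L] <- 1L
  array(out, dim = newd)
}

#' Centered crop or zero-pad
#'
#' Per axis, either the central `target` samples are kept (crop) or the
#' array is embedded centrally in zeros (pad); the start offset is
#' `floor((larger - smaller)/2)`, so crop after pad is the identity.
#'
#' @param x complex array.
#' @param target integer vector of target extents (recycled from the front;
#'   remaining axes keep their extent).
#' @return resized array.
#' @export
resize_center <- function(x, target) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  target <- as.integer(target)
  full <- d
  full[seq_along(target)] <- target
  idx_src <- vector("list", length(d))
  idx_dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    s <- d[ax]; t <- full[ax]
    if (t <= s) {
      idx_src[[ax]] <- floor((s - t) / 2) + seq_len(t)
      idx_dst[[ax]] <- seq_len(t)
    } else {
      idx_src[[ax]] <- seq_len(s)
      idx_dst[[ax]] <- floor((t - s) / 2) + seq_len(s)
    }
  }
  out <- array(0 + 0i, dim = full)
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(value = do.call(`[`, c(list(x), idx_src,
                                                      list(drop = FALSE))))))
  out
}
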