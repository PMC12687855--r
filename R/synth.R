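# Radial FLASH simulator: sequence parameters, turn-based and rational
# golden-angle trajectories, phantom scenes with smooth complex coil maps,
# motion and slice-reposition events, and an exact-DFT forward model (the
# generator deliberately shares no code with the gridding reconstruction
# path, so reconstruction tests are not inverse crimes).

#' Sequence parameter set
#'
#' Defaults emulate an RF-spoiled radial FLASH acquisition: 256 ADC samples
#' at 2x readout oversampling, 13 spokes per frame, matrix 192, TR 2.1 ms,
#' TE 1.25 ms, FOV 256 mm, turn-based pattern with 5 turns.  (ADC samples
#' and matrix are taken independently; 256 is the vendor value and not
#' exactly 2 x 192.)  For desk-scale tests use `matrix = 64`.
#'
#' @param adc_samples readout samples per spoke.
#' @param spokes_per_frame spokes per frame.
#' @param matrix reconstruction matrix size.
#' @param tr_ms repetition time in milliseconds.
#' @param te_ms echo time in milliseconds.
#' @param fov_mm field of view in millimeters.
#' @param turns number of turns of the turn-based pattern.
#' @param oversampling readout oversampling factor.
#' @return list of class `seq_params`.
#' @export
seq_params <- function(adc_samples = 256, spokes_per_frame = 13, matrix = 192,
                       tr_ms = 2.1, te_ms = 1.25, fov_mm = 256, turns = 5,
                       oversampling = 2) {
  if (spokes_per_frame < 1) stop("spokes_per_frame must be >= 1")
  structure(list(adc_samples = adc_samples,
                 spokes_per_frame = spokes_per_frame, matrix = matrix,
                 tr_ms = tr_ms, te_ms = te_ms, fov_mm = fov_mm,
                 turns = turns, oversampling = oversampling),
            class = "seq_params")
}

#' Acquisition time of one frame
#'
#' @param params a [seq_params()].
#' @return `spokes_per_frame * tr_ms`, in milliseconds.
#' @examples
#' frame_time(seq_params())  # 13 * 2.1 = 27.3
#' @export
frame_time <- function(params) {
  if (params$spokes_per_frame < 1) stop("spokes_per_frame must be >= 1")
  params$spokes_per_frame * params$tr_ms
}

traj_from_angles <- function(angles_per_frame, params) {
  nread <- params$adc_samples
  N <- params$matrix
  # radial samples span +/- N/2 in grid units at spacing N/nread
  t <- (seq_len(nread) - 1 - floor(nread / 2)) * (N / nread)
  nf <- length(angles_per_frame)
  nsp <- length(angles_per_frame[[1]])
  trj <- array(0 + 0i, dim = c(3, nread, nsp, nf))
  for (f in seq_len(nf)) {
    th <- angles_per_frame[[f]]
    for (s in seq_len(nsp)) {
      trj[1, , s, f] <- t * cos(th[s])
      trj[2, , s, f] <- t * sin(th[s])
    }
  }
  trj
}

#' Turn-based radial trajectory
#'
#' Frame `f` uses turn `f mod turns`.  Within a frame the spoke angles are
#' uniform over half the circle at spacing `pi / spokes_per_frame`; turn
#' `t` adds the offset `t * pi / (turns * spokes_per_frame)`, so the union
#' of `turns` consecutive frames covers `turns * spokes_per_frame`
#' uniformly spaced angles.
#'
#' @param params a [seq_params()].
#' @param n_frames number of frames.
#' @return complex trajectory array `(3, read, spoke, frame)` in grid units.
#' @export
traj_turn_based <- function(params, n_frames = params$turns) {
  if (params$turns < 1) stop("turns must be >= 1")
  nsp <- params$spokes_per_frame
  base <- (seq_len(nsp) - 1) * pi / nsp
  angles <- lapply(seq_len(n_frames) - 1, function(f) {
    turn <- f %% params$turns
    base + turn * pi / (params$turns * nsp)
  })
  traj_from_angles(angles, params)
}

fib <- function(n) {
  f <- c(1, 1)
  while (length(f) < n) f <- c(f, sum(utils::tail(f, 2)))
  f[n]
}

#' Rational golden-angle radial trajectory
#'
#' Spoke `i` (counted across frames) has angle
#' `i * pi * F(fib_index - 2) / F(fib_index)` with consecutive Fibonacci
#' numbers `F`; the angle sequence is periodic with period `F(fib_index)`
#' and approximates golden-angle sampling.
#'
#' @param params a [seq_params()].
#' @param fib_index Fibonacci index (`>= 3`); `F(7) = 13` gives the
#'   13-periodic small-golden-angle variant.
#' @param n_frames number of frames.
#' @return complex trajectory array `(3, read, spoke, frame)`.
#' @export
traj_golden_rational <- function(params, fib_index = 7, n_frames = 1) {
  if (fib_index < 3) stop("fib_index must be >= 3")
  inc <- pi * fib(fib_index - 2) / fib(fib_index)
  nsp <- params$spokes_per_frame
  angles <- lapply(seq_len(n_frames) - 1, function(f)
    ((f * nsp) + seq_len(nsp) - 1) * inc)
  traj_from_angles(angles, params)
}

gauss_coil <- function(N, cx, cy, sigma, phase_slope, phase0) {
  xs <- pixel_grid(N)
  X <- outer(xs, rep(1, N)); Y <- outer(rep(1, N), xs)
  r2 <- (X - cx)^2 + (Y - cy)^2
  mag <- exp(-r2 / (2 * sigma^2))
  ph <- phase0 + (phase_slope[1] * X + phase_slope[2] * Y) / N
  mag * exp(1i * ph)
}

make_coil_maps <- function(N, n_coils, ring_radius = 0.55, seed_offset = 0) {
  maps <- array(0 + 0i, dim = c(N, N, n_coils))
  for (j in seq_len(n_coils)) {
    phi <- 2 * pi * (j - 1) / n_coils + seed_offset
    cx <- ring_radius * N / 2 * cos(phi)
    cy <- ring_radius * N / 2 * sin(phi)
    # phase gradient points inward; opposite coils cancel on average
    maps[, , j] <- gauss_coil(N, cx, cy, sigma = 0.6 * N,
                              phase_slope = c(-2.5 * cos(phi), -2.5 * sin(phi)),
                              phase0 = phi / 2)
  }
  maps
}

# Rasterization uses 4x4 subpixel averaging (partial-volume effect at the
# edges), as a voxel of a real scan integrates the spin density over its
# extent; it also keeps the scene reasonably band-limited.
rasterize_ellipses <- function(N, ellipses, shift = c(0, 0), sub = 4) {
  xs <- pixel_grid(N)
  img <- matrix(0, N, N)
  offs <- (seq_len(sub) - 0.5) / sub - 0.5
  for (a in offs) {
    for (b in offs) {
      X <- outer(xs + a, rep(1, N)); Y <- outer(rep(1, N), xs + b)
      for (e in ellipses) {
        cx <- e$cx + shift[1]; cy <- e$cy + shift[2]
        ct <- cos(e$angle); st <- sin(e$angle)
        u <- (X - cx) * ct + (Y - cy) * st
        v <- -(X - cx) * st + (Y - cy) * ct
        inside <- (u / e$ax)^2 + (v / e$ay)^2 <= 1
        img[inside] <- img[inside] + e$intensity / sub^2
      }
    }
  }
  img
}

#' Phantom scene for the simulator
#'
#' A set of ellipses (default: a large water-filled tube with two inner
#' structures), smooth complex coil sensitivities on a ring of `n_coils`
#' receivers, a rigid-motion schedule (sinusoidal translation), and
#' optional slice-reposition events at which the coil maps change while
#' the phantom stays put.
#'
#' @param params a [seq_params()].
#' @param n_coils number of physical receive coils.
#' @param motion_amplitude peak translation in pixels (applied
#'   sinusoidally along x with the given period; 0 = static).
#' @param motion_period period of the motion in frames.
#' @param reposition_frames 1-based frame indices at which the coil maps
#'   switch to a rotated configuration.
#' @param ellipses optional list of ellipse specs
#'   (`cx, cy, ax, ay, angle, intensity`, pixel units) overriding the
#'   default phantom.
#' @return list of class `phantom_scene`.
#' @export
phantom_scene <- function(params, n_coils = 8, motion_amplitude = 0,
                          motion_period = 20, reposition_frames = integer(0),
                          ellipses = NULL) {
  N <- params$matrix
  if (is.null(ellipses)) {
    ellipses <- list(
      list(cx = 0, cy = 0, ax = 0.38 * N, ay = 0.33 * N, angle = 0,
           intensity = 1),
      list(cx = -0.12 * N, cy = 0.08 * N, ax = 0.09 * N, ay = 0.07 * N,
           angle = 0.5, intensity = 0.8),
      list(cx = 0.14 * N, cy = -0.10 * N, ax = 0.06 * N, ay = 0.10 * N,
           angle = -0.3, intensity = -0.5))
  }
  structure(list(params = params, n_coils = n_coils,
                 ellipses = ellipses,
                 motion_amplitude = motion_amplitude,
                 motion_period = motion_period,
                 reposition_frames = sort(unique(as.integer(reposition_frames))),
                 coil_maps = make_coil_maps(N, n_coils),
                 coil_maps_repositioned = make_coil_maps(N, n_coils,
                                                         seed_offset = pi / n_coils)),
            class = "phantom_scene")
}

scene_shift <- function(scene, frame) {
  if (scene$motion_amplitude == 0) return(c(0, 0))
  c(scene$motion_amplitude * sin(2 * pi * (frame - 1) / scene$motion_period), 0)
}

scene_coil_maps <- function(scene, frame) {
  n_events <- sum(scene$reposition_frames <= frame)
  if (n_events %% 2 == 1) scene$coil_maps_repositioned else scene$coil_maps
}

#' Ground-truth image of one frame
#'
#' The phantom at its frame-`frame` position times the root-sum-of-squares
#' of the active coil maps — the magnitude image a perfect reconstruction
#' would show.
#'
#' @param scene a [phantom_scene()].
#' @param frame 1-based frame index.
#' @return real matrix `(matrix, matrix)`.
#' @export
scene_truth <- function(scene, frame = 1) {
  N <- scene$params$matrix
  img <- rasterize_ellipses(N, scene$ellipses, scene_shift(scene, frame))
  cm <- scene_coil_maps(scene, frame)
  img * sqrt(apply(abs(cm)^2, c(1, 2), sum))
}

#' Simulate radial k-space data
#'
#' Per frame, the phantom (at its motion state) is multiplied by the active
#' coil maps and sampled by exact DFT summation at the trajectory
#' positions — shifted by the gradient-delay model `S n` per spoke when a
#' delay is given — and complex Gaussian noise of the stated standard
#' deviation is added.  The nominal (unshifted) trajectory is returned
#' alongside, as a scanner would report it.
#'
#' @param scene a [phantom_scene()].
#' @param trj nominal trajectory `(3, read, spoke, frame)` from
#'   [traj_turn_based()] or [traj_golden_rational()].
#' @param delay optional [delay_matrix()] injected into the sampling
#'   positions.
#' @param noise_sigma standard deviation of the additive complex noise
#'   (relative to a phantom of order-1 intensity).
#' @param seed RNG seed governing all randomness of the call.
#' @return list with `ksp` (array `(read, spoke, coil, frame)`), `trj`
#'   (the nominal trajectory), `truth` (array `(matrix, matrix, 1,
#'   frame)`) and `scene`.
#' @export
simulate_kspace <- function(scene, trj, delay = NULL, noise_sigma = 0,
                            seed = 1) {
  set.seed(seed)
  params <- scene$params
  N <- params$matrix
  d <- dim(trj)
  nread <- d[2]; nsp <- d[3]; nf <- if (length(d) == 4) d[4] else 1L
  nc <- scene$n_coils
  ksp <- array(0 + 0i, dim = c(nread, nsp, nc, nf))
  truth <- array(0, dim = c(N, N, 1, nf))
  Sm <- if (is.null(delay)) NULL else as.matrix(delay)
  for (f in seq_len(nf)) {
    img <- rasterize_ellipses(N, scene$ellipses, scene_shift(scene, f))
    cm <- scene_coil_maps(scene, f)
    coil_imgs <- matrix(0 + 0i, N * N, nc)
    for (j in seq_len(nc)) coil_imgs[, j] <- as.vector(img * cm[, , j])
    co <- traj_coords(trj, f)
    kx <- co$kx; ky <- co$ky
    if (!is.null(Sm)) {
      dirs <- traj_dirs(trj, f)
      dk <- stats::median(abs(diff(sqrt(kx[, 1]^2 + ky[, 1]^2))))
      shift <- Sm %*% dirs * dk
      kx <- sweep(kx, 2, shift[1, ], `+`)
      ky <- sweep(ky, 2, shift[2, ], `+`)
    }
    samples <- radial_dft_forward(coil_imgs, kx, ky, N)
    if (noise_sigma > 0) {
      nlev <- noise_sigma * N  # scale to the DFT sum magnitude
      samples <- samples +
        nlev * (array(stats::rnorm(length(samples)), dim = dim(samples)) +
                1i * array(stats::rnorm(length(samples)), dim = dim(samples)))
    }
    ksp[, , , f] <- samples
    truth[, , 1, f] <- scene_truth(scene, f)
  }
  list(ksp = ksp, trj = trj, truth = truth, scene = scene)
}

#' Normalized root-mean-square error after optimal scaling
#'
#' `||s*x - ref|| / ||ref||` minimized over the complex scalar `s`; the
#' absolute scale of a reconstruction is not meaningful, only its shape.
#'
#' @param x estimate (array).
#' @param ref reference (same shape).
#' @return nonnegative scalar.
#' @export
nrmse <- function(x, ref) {
  x <- as.vector(x); ref <- as.vector(ref)
  s <- sum(Conj(x) * ref) / sum(Mod(x)^2)
  sqrt(sum(Mod(s * x - ref)^2) / sum(Mod(ref)^2))
}
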