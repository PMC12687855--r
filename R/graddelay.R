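# Gradient-delay estimation and correction.  Delays are modeled as a
# symmetric 2x2 matrix S (units: readout samples) which, applied to the
# unit readout direction n of a spoke, gives the k-space shift S n of that
# spoke.  Estimation fits the three entries of S to per-spoke observations
# of the parallel shift component n' S n by least squares.

#' Construct a symmetric gradient-delay matrix
#'
#' @param s_xx,s_yy,s_xy entries of the symmetric 2x2 matrix, in units of
#'   readout samples.
#' @return object of class `delay_matrix`.
#' @export
delay_matrix <- function(s_xx, s_yy, s_xy = 0) {
  structure(list(s_xx = s_xx, s_yy = s_yy, s_xy = s_xy),
            class = "delay_matrix")
}

#' @export
as.matrix.delay_matrix <- function(x, ...) {
  matrix(c(x$s_xx, x$s_xy, x$s_xy, x$s_yy), 2, 2)
}

#' @export
print.delay_matrix <- function(x, ...) {
  cat("gradient-delay matrix (readout samples):\n")
  print(round(as.matrix(x), 4))
  if (!is.null(attr(x, "residual")))
    cat("fit residual:", signif(attr(x, "residual"), 3), "\n")
  invisible(x)
}

# Sub-sample position (in readout samples, relative to the spoke center) of
# the peak of the coil-summed power profile |s(t)|^2 of one spoke, by
# parabolic interpolation through the three samples around the maximum.
# For a (nearly) real-valued object |M(k)| peaks at the k-space origin, so
# the peak sits at minus the parallel delay component of the spoke.
spoke_power_peak <- function(spokes) {
  q <- rowSums(Mod(spokes)^2)
  i <- which.max(q)
  n <- length(q)
  if (i <= 1 || i >= n || any(q[(i - 1):(i + 1)] <= 0)) return(NA_real_)
  lq <- log(q[(i - 1):(i + 1)])  # log-parabola: exact for a Gaussian peak
  dd <- lq[1] - 2 * lq[2] + lq[3]
  if (dd >= 0) return(NA_real_)
  (i + 0.5 * (lq[1] - lq[3]) / dd) - 1 - floor(n / 2)
}

# Relative readout lag between two spokes of the same frame (in samples),
# from the mean phase increment of their image-domain cross-spectrum summed
# over coils.  Both spokes see the same object and coils, so coil phases
# cancel exactly; the lag measures the difference of the two parallel delay
# components.
spoke_pair_lag <- function(si, sj) {
  n <- nrow(si)
  C <- 0 + 0i
  for (cc in seq_len(ncol(si))) {
    a <- stats::fft(si[, cc], inverse = TRUE)
    b <- stats::fft(sj[, cc], inverse = TRUE)
    C <- C + a * Conj(b)
  }
  phi <- Arg(sum(C[-1] * Conj(C[-n])))
  -phi * n / (2 * pi)
}

#' Estimate the gradient-delay matrix of one frame
#'
#' Two kinds of shift observations enter a joint least-squares fit of the
#' three entries of `S`:
#' \itemize{
#'   \item per-spoke absolute parallel shifts `n' S n` from the sub-sample
#'     peak position of the coil-summed power profile (the k-space center
#'     of a spoke sits at minus its parallel shift);
#'   \item pairwise shift differences `n_i' S n_i - n_j' S n_j` from the
#'     phase slope of the cross-spectrum of two spokes, in which the coil
#'     phases cancel exactly.
#' }
#' The pairwise block determines the traceless (anisotropic) part of `S`
#' with high precision; the absolute block supplies the isotropic part.
#' At least 3 distinct spoke angles are required.
#'
#' @param ksp complex k-space `(read, spoke, coil)` of one frame.
#' @param trj trajectory of the same frame (nominal, uncorrected).
#' @param frame frame index within `trj`.
#' @return a [delay_matrix()] with attribute `residual` (RMS residual of
#'   the per-spoke absolute observations, in samples).
#' @export
estimate_delay <- function(ksp, trj, frame = 1) {
  dirs <- traj_dirs(trj, frame)
  nsp <- ncol(dirs)
  ang <- round(traj_angles(trj, frame), 6)
  if (length(unique(ang)) < 3)
    stop("rank deficiency: need spokes at >= 3 distinct angles, got ",
         length(unique(ang)))
  d <- dim(ksp)
  nc <- as.integer(prod(d) / (d[1] * d[2]))
  spoke <- function(s) matrix(ksp[, s, ], d[1], nc)
  nx <- dirs[1, ]; ny <- dirs[2, ]
  # absolute per-spoke observations
  obs_abs <- vapply(seq_len(nsp), function(s) -spoke_power_peak(spoke(s)),
                    numeric(1))
  ok <- !is.na(obs_abs)
  X_abs <- cbind(nx^2, ny^2, 2 * nx * ny)[ok, , drop = FALSE]
  obs_abs <- obs_abs[ok]
  # pairwise difference observations (traceless part)
  obs_d <- numeric(0)
  X_d <- NULL
  for (i in seq_len(nsp - 1)) {
    for (j in (i + 1):nsp) {
      obs_d <- c(obs_d, spoke_pair_lag(spoke(i), spoke(j)))
      X_d <- rbind(X_d, c(nx[i]^2 - nx[j]^2, ny[i]^2 - ny[j]^2,
                          2 * (nx[i] * ny[i] - nx[j] * ny[j])))
    }
  }
  # traceless solve from the pairwise block (trace pinned to zero), then
  # the isotropic part from the absolute block's residual mean
  co_d <- qr.solve(rbind(X_d, c(1, 1, 0)), c(obs_d, 0))
  f_traceless <- as.vector(X_abs %*% co_d)
  tr2 <- mean(obs_abs - f_traceless)  # (s_xx + s_yy)/2
  co <- co_d + c(tr2, tr2, 0)
  out <- delay_matrix(co[1], co[2], co[3])
  attr(out, "residual") <-
    sqrt(mean((obs_abs - as.vector(X_abs %*% co))^2))
  out
}

#' Shift a trajectory by the delay model
#'
#' Every spoke's sample positions are moved by `S n` along/about its unit
#' readout direction `n` (converted from readout samples to grid units by
#' the radial sample spacing), assigning the *measured* k-space positions
#' to the nominal trajectory.  Reconstructing with the corrected trajectory
#' undoes the delay-induced artifacts.
#'
#' @param trj trajectory array `(3, read, spoke[, frame])`.
#' @param S a [delay_matrix()].
#' @return corrected trajectory of the same shape.
#' @export
correct_trajectory <- function(trj, S) {
  Sm <- as.matrix(S)
  d <- dim(trj)
  d4 <- if (length(d) == 3) c(d, 1L) else d
  out <- array(trj, dim = d4)
  for (f in seq_len(d4[4])) {
    co <- traj_coords(out, f)
    dirs <- traj_dirs(out, f)
    dk <- stats::median(abs(diff(sqrt(co$kx[, 1]^2 + co$ky[, 1]^2))))
    shift <- Sm %*% dirs * dk  # grid units; 2 x nspokes
    for (s in seq_len(d4[3])) {
      out[1, , s, f] <- out[1, , s, f] + shift[1, s]
      out[2, , s, f] <- out[2, , s, f] + shift[2, s]
    }
  }
  array(out, dim = d)
}

#' Ellipse visualization of a delay matrix
#'
#' Eigendecomposition of the symmetric matrix: the absolute eigenvalues are
#' the principal axis lengths (delay strength) and the principal
#' eigenvector angle the orientation, in `[0, pi)`.  Rotating the readout
#' frame rotates the ellipse with it.
#'
#' @param S a [delay_matrix()].
#' @return list with `axis_lengths` (decreasing) and `orientation`
#'   (radians in `[0, pi)`), class `delay_ellipse`.
#' @export
delay_ellipse <- function(S) {
  e <- eigen(as.matrix(S), symmetric = TRUE)
  ord <- order(abs(e$values), decreasing = TRUE)
  v <- e$vectors[, ord[1]]
  structure(list(axis_lengths = abs(e$values)[ord],
                 orientation = atan2(v[2], v[1]) %% pi),
            class = "delay_ellipse")
}

#' @export
print.delay_ellipse <- function(x, ...) {
  cat("delay ellipse: axes", signif(x$axis_lengths, 4), "samples, orientation",
      signif(x$orientation, 4), "rad\n")
  invisible(x)
}

#' Plot a delay ellipse
#'
#' @param x a `delay_ellipse`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.delay_ellipse <- function(x, ...) {
  th <- seq(0, 2 * pi, length.out = 200)
  a <- x$axis_lengths[1]; b <- x$axis_lengths[2]; phi <- x$orientation
  ex <- a * cos(th) * cos(phi) - b * sin(th) * sin(phi)
  ey <- a * cos(th) * sin(phi) + b * sin(th) * cos(phi)
  graphics::plot(ex, ey, type = "l", asp = 1,
                 xlab = "kx shift (samples)", ylab = "ky shift (samples)", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
}

#' Exponentially smoothed per-frame delay estimation
#'
#' Streams a delay estimate across frames: `S_f = decay * S_{f-1} +
#' (1 - decay) * estimate(frame f)`.  With `decay = 0` each frame stands
#' alone.
#'
#' @param ksp_frames list of k-space frames.
#' @param trj trajectory array with matching frames.
#' @param decay smoothing factor in `[0, 1)` (default 0.5).
#' @return list of [delay_matrix()] objects, one per frame.
#' @export
estimate_delay_stream <- function(ksp_frames, trj, decay = 0.5) {
  out <- vector("list", length(ksp_frames))
  prev <- NULL
  for (f in seq_along(ksp_frames)) {
    est <- estimate_delay(ksp_frames[[f]], trj, frame = f)
    if (!is.null(prev) && decay > 0) {
      m <- decay * as.matrix(prev) + (1 - decay) * as.matrix(est)
      est <- delay_matrix(m[1, 1], m[2, 2], m[1, 2])
    }
    out[[f]] <- est
    prev <- est
  }
  out
}
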