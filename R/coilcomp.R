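# SVD coil compression, per-frame application, and temporal alignment of
# the compression matrices (geometric coil compression for real-time use).

frame_data_matrix <- function(ksp) {
  d <- dim(ksp)
  if (is.null(d) || length(d) < 3)
    stop("expected k-space of shape (read, spoke, coil)")
  matrix(ksp, d[1] * d[2], d[3])
}

#' SVD compression matrix of one frame
#'
#' Columns are the top right-singular vectors of the `(samples x coils)`
#' data matrix, i.e. the rank-`n_virtual` projection capturing maximal
#' signal energy.  All samples of the frame serve as calibration data
#' (radial sampling is densest at the k-space center, so the frame is
#' inherently self-calibrating).
#'
#' @param ksp complex array `(read, spoke, coil)`.
#' @param n_virtual number of virtual coils, `<=` physical coils.
#' @return complex matrix `(coils x n_virtual)` with orthonormal columns.
#' @export
cc_svd <- function(ksp, n_virtual) {
  D <- frame_data_matrix(ksp)
  nc <- ncol(D)
  if (n_virtual > nc)
    stop("n_virtual (", n_virtual, ") exceeds physical coil count (", nc, ")")
  sv <- svd(D, nu = 0, nv = n_virtual)
  sv$v
}

#' Apply a compression matrix to k-space data
#'
#' @param ksp complex array `(read, spoke, coil)`.
#' @param matrix compression matrix `(coils x n_virtual)`.
#' @return compressed array `(read, spoke, n_virtual)`.
#' @export
ccapply <- function(ksp, matrix) {
  d <- dim(ksp)
  if (d[3] != nrow(matrix))
    stop("matrix expects ", nrow(matrix), " coils, data has ", d[3])
  out <- frame_data_matrix(ksp) %*% matrix
  array(out, dim = c(d[1], d[2], ncol(matrix)))
}

procrustes_rotation <- function(current, previous) {
  # unitary Q minimizing || current %*% Q - previous ||_F
  m <- Conj(t(current)) %*% previous
  sv <- svd(m)
  sv$u %*% Conj(t(sv$v))
}

#' Align a series of compression matrices along time
#'
#' The SVD basis is unique only up to a unitary rotation of the virtual
#' coils, so independently compressed frames can jump between equivalent
#' bases and make the virtual coil profiles (and the images) flicker.
#' Alignment right-multiplies each matrix by the unitary rotation that
#' brings it closest (in Frobenius norm) to its aligned predecessor — an
#' orthogonal Procrustes problem solved by SVD.  Column spaces, and hence
#' the compressed signal energy, are unchanged.  The pass is strictly
#' causal: each frame only sees its predecessor.
#'
#' @param matrices list of `(coils x n_virtual)` matrices, one per frame.
#' @return list of aligned matrices (first frame unchanged), with
#'   attribute `"aligned" = TRUE`.
#' @export
align_matrices <- function(matrices) {
  if (length(matrices) == 0) stop("empty series")
  out <- matrices
  for (f in seq_along(matrices)[-1]) {
    Q <- procrustes_rotation(out[[f]], out[[f - 1L]])
    out[[f]] <- out[[f]] %*% Q
  }
  attr(out, "aligned") <- TRUE
  out
}

#' Coil-compress a series of frames
#'
#' Three modes mirror the real-time strategies: `"static"` computes one
#' matrix from the first frame and reuses it; `"dynamic-unaligned"`
#' recomputes the SVD every frame; `"dynamic-aligned"` recomputes and
#' aligns each matrix to its predecessor ([align_matrices()]) causally.
#'
#' @param frames list of k-space frames `(read, spoke, coil)`, or a 4-d
#'   array with frames on the last axis.
#' @param n_virtual number of virtual coils.
#' @param mode compression mode.
#' @return list with `frames` (compressed k-space frames) and `matrices`
#'   (per-frame compression matrices actually applied).
#' @export
cc_stream <- function(frames, n_virtual,
                      mode = c("static", "dynamic-unaligned", "dynamic-aligned")) {
  mode <- match.arg(mode)
  if (is.array(frames) && length(dim(frames)) == 4) {
    nf <- dim(frames)[4]
    frames <- lapply(seq_len(nf), function(f) frames[, , , f, drop = TRUE])
  }
  mats <- vector("list", length(frames))
  prev <- NULL
  for (f in seq_along(frames)) {
    m <- if (mode == "static") {
      if (f == 1) cc_svd(frames[[f]], n_virtual) else mats[[1]]
    } else {
      cc_svd(frames[[f]], n_virtual)
    }
    if (mode == "dynamic-aligned" && !is.null(prev))
      m <- m %*% procrustes_rotation(m, prev)
    mats[[f]] <- m
    prev <- m
  }
  list(frames = mapply(ccapply, frames, mats, SIMPLIFY = FALSE),
       matrices = mats)
}

#' Frame-to-frame jumps of virtual coil profiles
#'
#' Mean L2 distance between the compressed k-space of consecutive frames of
#' a series, the quantity in which unaligned dynamic compression shows
#' discontinuities ("flickering").
#'
#' @param frames list of compressed frames.
#' @return numeric vector of length `length(frames) - 1`.
#' @export
profile_jumps <- function(frames) {
  vapply(seq_along(frames)[-1], function(f)
    sqrt(mean(Mod(frames[[f]] - frames[[f - 1]])^2)), numeric(1))
}
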