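# Centered unitary FFTs over an arbitrary subset of axes.

shift_index <- function(n, inverse = FALSE) {
  h <- if (inverse) ceiling(n / 2) else floor(n / 2)
  ((seq_len(n) - 1L + h) %% n) + 1L
}

shift_axis <- function(x, axis, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  n <- d[axis + 1L]
  if (n == 1L) return(x)
  idx <- lapply(d, seq_len)
  idx[[axis + 1L]] <- shift_index(n, inverse)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Swap the two halves of an array along selected axes
#'
#' `fftshift` moves the zero-frequency sample to the array center;
#' `inverse = TRUE` undoes it (relevant for odd extents).
#'
#' @param x an array.
#' @param axes 0-based axis indices (default: all axes with extent > 1).
#' @param inverse apply the inverse shift.
#' @return shifted array.
#' @export
fftshift <- function(x, axes = NULL, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (is.null(axes)) axes <- which(d > 1L) - 1L
  for (ax in axes) x <- shift_axis(x, ax, inverse)
  x
}

fft_axis <- function(x, axis, inverse) {
  d <- dim(x)
  if (is.null(d)) d <- c(length(x))
  n <- d[axis + 1L]
  if (n == 1L) return(x)
  perm <- c(axis + 1L, seq_along(d)[-(axis + 1L)])
  y <- aperm(array(x, dim = d), perm)
  dim(y) <- c(n, length(x) / n)
  y <- stats::mvfft(y, inverse = inverse)
  dim(y) <- d[perm]
  aperm(y, order(perm))
}

#' Discrete Fourier transform over selected axes
#'
#' Unitary (norm-preserving) DFT, centered by default: both the image and
#' frequency origin sit at index `floor(n/2)` (0-based), matching the
#' convention used by the gridding and reconstruction operators.
#'
#' @param x complex array.
#' @param flags bitmask of the transformed axes ([bitmask_encode()]).
#' @param inverse inverse transform.
#' @param centered centered convention (default `TRUE`).
#' @return transformed array of the same shape.
#' @export
fft_md <- function(x, flags, inverse = FALSE, centered = TRUE) {
  axes <- bitmask_decode(flags)
  if (length(axes) == 0) stop("empty set of transform axes")
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  axes <- axes[axes + 1L <= length(d)]
  scale <- 1
  for (ax in axes) {
    n <- d[ax + 1L]
    if (n <= 1L) next
    if (centered) x <- shift_axis(x, ax, inverse = TRUE)
    x <- fft_axis(x, ax, inverse)
    if (centered) x <- shift_axis(x, ax, inverse = FALSE)
    scale <- scale * n
  }
  x / sqrt(scale)
}
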