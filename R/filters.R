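# Post-processing filters: causal temporal median, frame-wise non-local
# means.

window_median <- function(stack) {
  # stack: npix x L matrix (possibly complex); per-pixel median
  if (is.complex(stack)) {
    complex(real = apply(Re(stack), 1, stats::median),
            imaginary = apply(Im(stack), 1, stats::median))
  } else {
    apply(stack, 1, stats::median)
  }
}

#' Causal temporal median filter
#'
#' Per-pixel median over the last `L` frames (the current frame and its
#' `L - 1` predecessors; the first frames use all frames seen so far).
#' Causality makes the filter usable in a real-time stream at the cost of
#' delaying content changes by about `floor(L/2)` frames.
#'
#' @param x array with frames along `frame_axis`.
#' @param L odd window length.
#' @param frame_axis 0-based frame axis (default 3).
#' @return filtered array of the same shape.
#' @export
median_filter_temporal <- function(x, L, frame_axis = 3) {
  if (L %% 2 == 0 || L < 1) stop("window length must be odd and >= 1")
  d <- md_dims(x)
  nf <- d[frame_axis + 1L]
  out <- x
  for (f in seq_len(nf)) {
    lo <- max(1L, f - L + 1L)
    win <- vapply(lo:f, function(g)
      as.vector(extract_slice(x, frame_axis, g - 1L)),
      FUN.VALUE = complex(prod(d) / nf))
    med <- window_median(matrix(win, ncol = f - lo + 1L))
    out <- insert_slice(out, frame_axis, f - 1L,
                        array(med, dim = dim(extract_slice(x, frame_axis, 0L))))
  }
  out
}

# Stream-aware form: state is the ring buffer of the last L frames.
median_tool_step <- function(state, inputs, opts) {
  L <- if (is.null(opts$L)) 5L else as.integer(opts$L)
  if (L %% 2 == 0) stop("window length must be odd")
  frame <- inputs[[1]]
  buf <- if (is.null(state)) list() else state
  buf[[length(buf) + 1L]] <- frame
  if (length(buf) > L) buf <- buf[-1]
  stack <- vapply(buf, as.vector, FUN.VALUE = complex(length(frame)))
  med <- window_median(matrix(stack, ncol = length(buf)))
  list(state = buf, output = array(med, dim = dim(frame)))
}

# Box sum over k x k neighborhoods with replicated borders (integral image).
box_sum <- function(m, k) {
  h <- k %/% 2
  n1 <- nrow(m); n2 <- ncol(m)
  p <- m[c(rep(1, h), 1:n1, rep(n1, h)), c(rep(1, h), 1:n2, rep(n2, h))]
  ii <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  Z <- matrix(0, nrow(p) + 1, ncol(p) + 1)
  Z[-1, -1] <- ii
  r1 <- 1:n1; r2 <- r1 + k
  c1 <- 1:n2; c2 <- c1 + k
  Z[r2, c2] - Z[r1, c2] - Z[r2, c1] + Z[r1, c1]
}

shift_pad <- function(m, dx, dy) {
  n1 <- nrow(m); n2 <- ncol(m)
  ix <- pmin(pmax(1:n1 + dx, 1), n1)
  iy <- pmin(pmax(1:n2 + dy, 1), n2)
  m[ix, iy]
}

# Robust image noise estimate: response of the Laplacian-difference mask
# has standard deviation 6*sigma on i.i.d. noise and suppresses smooth
# structure; the MAD makes the estimate insensitive to edges.
estimate_noise_sd <- function(img) {
  n1 <- nrow(img); n2 <- ncol(img)
  if (n1 < 3 || n2 < 3) return(0)
  M <- img[2:(n1 - 1), 2:(n2 - 1)] * 4 -
    2 * (img[1:(n1 - 2), 2:(n2 - 1)] + img[3:n1, 2:(n2 - 1)] +
         img[2:(n1 - 1), 1:(n2 - 2)] + img[2:(n1 - 1), 3:n2]) +
    img[1:(n1 - 2), 1:(n2 - 2)] + img[1:(n1 - 2), 3:n2] +
    img[3:n1, 1:(n2 - 2)] + img[3:n1, 3:n2]
  stats::mad(as.vector(M)) / 6
}

#' Frame-wise non-local means filter
#'
#' Each pixel is replaced by a weighted average of pixels with similar
#' patches; a candidate at offset `(dx, dy)` gets weight
#' `exp(-max(d - 2*sigma^2, 0) / h^2)` with `d` the mean squared
#' difference of the two patches and `sigma` a robust estimate of the
#' image noise, so that the expected patch distance of two noisy copies
#' of the same content costs nothing.  The filter is strictly frame-wise
#' (no temporal mixing).
#'
#' @param frame 2-D real matrix (complex input is reduced to its magnitude).
#' @param patch odd patch edge length (default 5).
#' @param search odd search-window edge length (default 11).
#' @param h filtering strength; default `0.4 * sigma` with `sigma` the
#'   MAD-based noise estimate of the frame.
#' @return filtered real matrix.
#' @export
nlm_filter <- function(frame, patch = 5, search = 11, h = NULL) {
  img <- if (is.complex(frame)) Mod(frame) else frame
  img <- matrix(as.vector(img),
                nrow = dim(as.array(frame))[1])
  sigma <- estimate_noise_sd(img)
  if (is.null(h)) h <- 0.4 * sigma + 1e-12
  hs <- search %/% 2
  num <- matrix(0, nrow(img), ncol(img))
  den <- matrix(0, nrow(img), ncol(img))
  np <- patch * patch
  for (dx in -hs:hs) {
    for (dy in -hs:hs) {
      sh <- shift_pad(img, dx, dy)
      d2 <- box_sum((img - sh)^2, patch) / np
      w <- exp(-pmax(d2 - 2 * sigma^2, 0) / h^2)
      num <- num + w * sh
      den <- den + w
    }
  }
  num / den
}
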