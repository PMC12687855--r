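# Maximum number of array dimensions carried by the file format and the
# wire protocol.  Trailing dimensions beyond the semantic rank have extent 1.
MD_MAX_DIMS <- 16L

#' Padded dimension vector of an array
#'
#' Returns the extents of `x` padded with trailing ones to `n` entries, the
#' convention used by the cfl file format and the stream protocol.
#'
#' @param x an array (or vector, treated as rank 1).
#' @param n number of entries to pad to (default 16).
#' @return integer vector of length `n`.
#' @export
md_dims <- function(x, n = MD_MAX_DIMS) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  d <- as.integer(d)
  if (length(d) > n)
    stop("array has more than ", n, " dimensions")
  c(d, rep(1L, n - length(d)))
}

md_check_dims <- function(dims) {
  dims <- as.integer(dims)
  if (any(is.na(dims)) || any(dims < 1L))
    stop("invalid dimensions: all extents must be >= 1")
  dims
}

#' Encode a set of axes as a bitmask
#'
#' Axis indices are 0-based: axis `i` contributes `2^i`.  The empty set
#' encodes to 0.
#'
#' @param axes integer vector of distinct 0-based axis indices.
#' @return a single non-negative number.
#' @seealso [bitmask_decode()]
#' @examples
#' bitmask_encode(c(1, 2))  # 6
#' @export
bitmask_encode <- function(axes) {
  if (length(axes) == 0) return(0)
  axes <- as.integer(axes)
  if (any(axes < 0)) stop("axis indices must be >= 0")
  if (anyDuplicated(axes)) stop("axis indices must be distinct")
  sum(2^axes)
}

#' Decode a bitmask into the set of axes it selects
#'
#' @param flags non-negative integer bitmask.
#' @return sorted integer vector of 0-based axis indices.
#' @examples
#' bitmask_decode(6)  # c(1, 2)
#' @export
bitmask_decode <- function(flags) {
  flags <- as.numeric(flags)
  if (length(flags) != 1 || is.na(flags) || flags < 0 || flags != floor(flags))
    stop("flags must be a single non-negative integer")
  axes <- integer(0)
  i <- 0L
  while (flags > 0) {
    if (flags %% 2 == 1) axes <- c(axes, i)
    flags <- flags %/% 2
    i <- i + 1L
  }
  axes
}

#' Serial number of a slice
#'
#' Flattens the multi-index `a` over the selected axes into a single serial
#' number.  The smallest selected axis varies fastest:
#' `c = sum_k a_k * prod_{l<k} N_{S(l)}`, where `S` is the sorted set of
#' selected axes and `N` the parent extents.
#'
#' @param a integer vector, 0-based multi-index over the selected axes, in
#'   order of increasing axis index.
#' @param dims extents of the parent array.
#' @param axes 0-based indices of the selected axes.
#' @return 0-based serial number.
#' @seealso [serial_to_index()]
#' @export
slice_serial <- function(a, dims, axes) {
  axes <- sort(as.integer(axes))
  dims <- md_check_dims(dims)
  if (length(a) != length(axes))
    stop("multi-index length does not match number of selected axes")
  n <- dims[axes + 1L]
  a <- as.integer(a)
  for (k in seq_along(a)) {
    if (a[k] < 0 || a[k] >= n[k])
      stop("index ", a[k], " out of range on axis ", axes[k])
  }
  if (length(a) == 0) return(0)
  sum(a * cumprod(c(1, n[-length(n)])))
}

#' Multi-index of a slice serial number
#'
#' Inverse of [slice_serial()].
#'
#' @inheritParams slice_serial
#' @param serial 0-based serial number.
#' @return integer vector, 0-based multi-index over the sorted selected axes.
#' @export
serial_to_index <- function(serial, dims, axes) {
  axes <- sort(as.integer(axes))
  dims <- md_check_dims(dims)
  n <- dims[axes + 1L]
  total <- prod(n)
  if (serial < 0 || serial >= total)
    stop("serial number ", serial, " out of range [0, ", total, ")")
  a <- integer(length(axes))
  for (k in seq_along(axes)) {
    a[k] <- serial %% n[k]
    serial <- serial %/% n[k]
  }
  a
}

#' Number of slices selected by a set of axes
#'
#' @inheritParams slice_serial
#' @return product of the extents of the selected axes.
#' @export
slice_count <- function(dims, axes) {
  dims <- md_check_dims(dims)
  axes <- as.integer(axes)
  if (length(axes) == 0) return(1)
  prod(dims[axes + 1L])
}

#' Extract one slice of an array
#'
#' Returns the sub-array obtained by fixing the indices of the selected axes
#' to the multi-index of serial number `serial`.  Selected axes are kept with
#' extent 1, so the slice has the same rank as the parent.
#'
#' @param x an array.
#' @param axes 0-based indices of the selected (sliced) axes.
#' @param serial 0-based serial number of the slice.
#' @return array with the selected axes collapsed to extent 1.
#' @seealso [insert_slice()], [slice_serial()]
#' @export
extract_slice <- function(x, axes, serial) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  axes <- sort(as.integer(axes))
  if (length(axes) == 0) {
    if (serial != 0) stop("serial number ", serial, " out of range [0, 1)")
    return(x)
  }
  if (any(axes + 1L > length(d))) {
    # axes beyond the stored rank have extent 1
    d <- c(d, rep(1L, max(axes) + 1L - length(d)))
    x <- array(x, dim = d)
  }
  a <- serial_to_index(serial, d, axes)
  idx <- lapply(d, seq_len)
  for (k in seq_along(axes)) idx[[axes[k] + 1L]] <- a[k] + 1L
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  out
}

#' Insert one slice into an array
#'
#' Inverse of [extract_slice()]: writes `slice` at the position given by
#' `serial` on the selected axes.
#'
#' @inheritParams extract_slice
#' @param slice array with extent 1 on all selected axes.
#' @return the modified array.
#' @export
insert_slice <- function(x, axes, serial, slice) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  axes <- sort(as.integer(axes))
  if (length(axes) == 0) return(slice)
  orig_dim <- d
  if (any(axes + 1L > length(d))) {
    d <- c(d, rep(1L, max(axes) + 1L - length(d)))
    x <- array(x, dim = d)
  }
  a <- serial_to_index(serial, d, axes)
  idx <- lapply(d, seq_len)
  for (k in seq_along(axes)) idx[[axes[k] + 1L]] <- a[k] + 1L
  out <- do.call(`[<-`, c(list(x), idx, list(value = slice)))
  array(out, dim = orig_dim)
}

# Linear (1-based) indices of the elements of one slice within the parent
# array, in the slice's own column-major order.  Assigning through these
# indices (`x[ind] <- slice`) updates a locally owned array in place,
# which matters in streaming loops.
slice_linear_indices <- function(dims, axes, serial) {
  dims <- as.integer(dims)
  axes <- sort(as.integer(axes))
  a <- serial_to_index(serial, dims, axes)
  stride <- cumprod(c(1, dims[-length(dims)]))
  offs <- vector("list", length(dims))
  for (ax in seq_along(dims)) {
    k <- match(ax - 1L, axes)
    pos <- if (!is.na(k)) a[k] else 0:(dims[ax] - 1L)
    offs[[ax]] <- pos * stride[ax]
  }
  ind <- offs[[1]]
  for (ax in seq_along(dims)[-1])
    ind <- as.vector(outer(ind, offs[[ax]], `+`))
  ind + 1
}

#' Reassemble an array from its slices
#'
#' @param slices list of slices in serial order, as produced by
#'   [extract_slice()].
#' @param dims extents of the full array.
#' @param axes 0-based indices of the sliced axes.
#' @return the reassembled array.
#' @export
md_reassemble <- function(slices, dims, axes) {
  dims <- md_check_dims(dims)
  dims <- dims[seq_len(max(which(dims > 1L), 1L))]
  nsl <- slice_count(dims, axes)
  if (length(slices) != nsl)
    stop("expected ", nsl, " slices, got ", length(slices))
  x <- array(0 + 0i, dim = dims)
  for (s in seq_along(slices))
    x <- insert_slice(x, axes, s - 1L, slices[[s]])
  x
}

#' Round complex values to single precision
#'
#' The file format and wire protocol store complex single precision; this
#' helper applies the same quantization in memory, so that round trips can
#' be compared bit-exactly.
#'
#' @param x complex vector or array.
#' @return `x` with real and imaginary parts rounded to float32.
#' @export
md_float32 <- function(x) {
  d <- dim(x)
  v <- c(rbind(Re(x), Im(x)))
  v <- readBin(writeBin(v, raw(), size = 4L), "double", n = length(v), size = 4L)
  out <- complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
  if (!is.null(d)) dim(out) <- d
  out
}
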