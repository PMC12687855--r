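# Wire protocol for streamed md-arrays.
#
# A stream starts with a static header whose first two lines are identical to
# the cfl .hdr header for the same dimensions, followed by optional comment
# lines and a stream header line, terminated by a blank line:
#
#   # Dimensions
#   <16 space-separated extents>
#   # shared <path>            (shared-storage transport only)
#   # meta <key>=<value>       (optional, repeated)
#   # stream <flags> <binary|shared>
#   <blank line>
#
# Each slice is then announced by a one-line message
#
#   slice <serial> <payload-bytes> <n-meta>
#
# followed by <n-meta> lines of per-slice "key=value" metadata and, in binary
# (inline) mode, by <payload-bytes> of raw little-endian complex float32
# payload.  In shared-storage mode the payload is written to the shared file
# at offset serial * slice_bytes; the payload (inline or shared) is always
# flushed to the transport *before* the slice message, so a consumer that has
# seen the message can rely on the data being complete.  End of stream is a
# clean close after the last slice; a close inside a payload is a truncation
# error.

is_stdio <- function(name) identical(name, "-")
is_fifo_path <- function(name) is.character(name) && grepl("\\.fifo$", name)

ensure_fifo <- function(path) {
  if (!file.exists(path)) {
    status <- suppressWarnings(system2("mkfifo", shQuote(path),
                                       stderr = FALSE))
    # a concurrent endpoint may have created it first; that is fine
    if (status != 0 && !file.exists(path))
      stop("could not create FIFO ", path)
  }
  invisible(path)
}

open_sink <- function(sink) {
  if (inherits(sink, "connection")) return(list(con = sink, own = FALSE))
  if (is_stdio(sink)) return(list(con = file("stdout", open = "wb"), own = TRUE))
  if (is_fifo_path(sink)) {
    ensure_fifo(sink)
    return(list(con = fifo(sink, open = "wb", blocking = TRUE), own = TRUE))
  }
  list(con = file(sink, open = "wb"), own = TRUE)
}

open_source <- function(source) {
  if (inherits(source, "connection")) return(list(con = source, own = FALSE))
  if (is_stdio(source)) return(list(con = file("stdin", open = "rb"), own = TRUE))
  if (is_fifo_path(source)) {
    ensure_fifo(source)
    return(list(con = fifo(source, open = "rb", blocking = TRUE), own = TRUE))
  }
  list(con = file(source, open = "rb"), own = TRUE)
}

# Read one newline-terminated line from a binary connection.  Returns NULL on
# a clean end of stream (no bytes at all).
read_line_raw <- function(con) {
  bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0) {
      if (length(bytes) == 0) return(NULL)
      stop("stream ended in the middle of a protocol line")
    }
    if (b == as.raw(10L)) break
    bytes <- c(bytes, b)
  }
  rawToChar(bytes)
}

slice_dims_of <- function(dims, axes) {
  d <- dims
  if (length(axes)) d[axes + 1L] <- 1L
  d
}

#' Open a stream writer
#'
#' Emits the static header (identical in its first two lines to the cfl
#' `.hdr` file for the same dimensions) and the stream header, then accepts
#' slices via [write_slice()].
#'
#' @param sink `"-"` for standard output, a path ending in `.fifo` (created
#'   if absent), any other file path, or an open binary connection.
#' @param dims extents of the full array (padded internally to 16).
#' @param flags bitmask of the streamed (sliced) axes, see
#'   [bitmask_encode()].
#' @param binary if `TRUE`, slice payloads are inlined into the byte stream
#'   (the binary version of the protocol, usable across machines); if
#'   `FALSE` (default) payloads travel through a shared-storage file named
#'   in the header and only completion messages use the byte stream.
#' @param shared_path path of the shared-storage file (shared mode only;
#'   default: a temporary file).
#' @param meta optional named character vector of stream-level metadata.
#' @return a writer handle.
#' @seealso [write_slice()], [close_stream()], [open_stream_reader()]
#' @export
open_stream_writer <- function(sink, dims, flags, binary = FALSE,
                               shared_path = NULL, meta = NULL) {
  dims16 <- md_check_dims(dims)
  dims16 <- c(dims16, rep(1L, MD_MAX_DIMS - length(dims16)))
  axes <- bitmask_decode(flags)
  if (length(axes) && any(dims16[axes + 1L] < 1L))
    stop("stream flags select an invalid axis")
  s <- open_sink(sink)
  w <- new.env(parent = emptyenv())
  w$con <- s$con
  w$own <- s$own
  w$dims <- dims16
  w$axes <- axes
  w$flags <- flags
  w$binary <- isTRUE(binary)
  w$slice_dims <- slice_dims_of(dims16, axes)
  w$slice_len <- prod(w$slice_dims)
  w$n_slices <- slice_count(dims16, axes)
  w$next_index <- 0L
  w$closed <- FALSE

  hdr <- cfl_header_text(dims16)
  if (!w$binary) {
    if (is.null(shared_path)) shared_path <- tempfile(fileext = ".shm")
    w$shared_path <- shared_path
    # preallocate the full region so readers can seek anywhere
    shcon <- file(shared_path, "wb")
    writeBin(raw(8 * prod(dims16)), shcon)
    close(shcon)
    w$shared_con <- file(shared_path, "r+b")
    hdr <- paste0(hdr, "# shared ", shared_path, "\n")
  }
  for (key in names(meta))
    hdr <- paste0(hdr, "# meta ", key, "=", meta[[key]], "\n")
  hdr <- paste0(hdr, "# stream ", format(flags, scientific = FALSE), " ",
                if (w$binary) "binary" else "shared", "\n\n")
  writeBin(charToRaw(hdr), w$con)
  flush(w$con)
  class(w) <- "mdstream_writer"
  w
}

#' Write one slice to a stream
#'
#' Slices must be written in serial order starting at 0.  The payload is
#' made fully readable (inline bytes flushed, or the shared-storage region
#' populated and flushed) before the slice message itself is emitted.
#'
#' @param writer handle from [open_stream_writer()].
#' @param slice complex array whose extents match the full dimensions with
#'   the streamed axes collapsed to 1.
#' @param meta optional named character vector of per-slice metadata.
#' @param index serial index of the slice; defaults to the next expected.
#' @return the writer, invisibly.
#' @export
write_slice <- function(writer, slice, meta = NULL, index = NULL) {
  if (writer$closed) stop("writer is closed")
  if (is.null(index)) index <- writer$next_index
  if (index != writer$next_index)
    stop("out-of-order slice index ", index, " (expected ", writer$next_index, ")")
  if (index >= writer$n_slices)
    stop("slice index ", index, " out of range [0, ", writer$n_slices, ")")
  if (length(slice) != writer$slice_len)
    stop("slice has ", length(slice), " values, expected ", writer$slice_len)
  payload <- c(rbind(Re(slice), Im(slice)))
  nbytes <- 0L
  if (writer$binary) {
    nbytes <- 8L * writer$slice_len
  } else {
    seek(writer$shared_con, where = index * 8 * writer$slice_len, rw = "write")
    writeBin(payload, writer$shared_con, size = 4L, endian = "little")
    flush(writer$shared_con)
  }
  nm <- length(meta)
  msg <- paste0("slice ", format(index, scientific = FALSE), " ", nbytes, " ", nm, "\n")
  if (nm) {
    msg <- paste0(msg, paste0(names(meta), "=", unname(meta), "\n", collapse = ""))
  }
  writeBin(charToRaw(msg), writer$con)
  if (writer$binary)
    writeBin(payload, writer$con, size = 4L, endian = "little")
  flush(writer$con)
  writer$next_index <- writer$next_index + 1L
  invisible(writer)
}

#' Close a stream endpoint
#'
#' For writers this signals a clean end of stream; for readers it releases
#' the transport.
#'
#' @param handle a writer or reader handle.
#' @export
close_stream <- function(handle) {
  if (!isTRUE(handle$closed)) {
    if (!is.null(handle$shared_con)) try(close(handle$shared_con), silent = TRUE)
    if (isTRUE(handle$own)) try(close(handle$con), silent = TRUE)
    handle$closed <- TRUE
  }
  invisible(NULL)
}

#' Open a stream reader
#'
#' Parses the static and stream headers and returns a handle from which
#' slices can be pulled with [read_slice()].  Opening blocks until the
#' producer has emitted the header.
#'
#' @param source `"-"` for standard input, a `.fifo` path, a file path
#'   holding a captured stream, or an open binary connection.
#' @return a reader handle with fields `dims` (16 extents), `flags`,
#'   `axes`, `binary`, `meta`, `n_slices`.
#' @export
open_stream_reader <- function(source) {
  s <- open_source(source)
  r <- new.env(parent = emptyenv())
  r$con <- s$con
  r$own <- s$own
  first <- read_line_raw(r$con)
  if (is.null(first) || !grepl("^# Dimensions", first))
    stop("malformed stream header: expected '# Dimensions'")
  dims_line <- read_line_raw(r$con)
  if (is.null(dims_line)) stop("malformed stream header: missing extents")
  r$dims <- parse_cfl_header(c(first, dims_line))
  r$meta <- character(0)
  r$binary <- NA
  repeat {
    line <- read_line_raw(r$con)
    if (is.null(line)) stop("malformed stream header: unterminated")
    if (line == "") break
    if (grepl("^# shared ", line)) {
      r$shared_path <- sub("^# shared ", "", line)
    } else if (grepl("^# meta ", line)) {
      kv <- sub("^# meta ", "", line)
      key <- sub("=.*$", "", kv)
      r$meta[key] <- sub("^[^=]*=", "", kv)
    } else if (grepl("^# stream ", line)) {
      parts <- strsplit(sub("^# stream ", "", line), "\\s+")[[1]]
      r$flags <- as.numeric(parts[1])
      r$binary <- identical(parts[2], "binary")
    }
    # unknown comment lines are preserved but ignored
  }
  if (is.na(r$binary)) stop("malformed stream header: no '# stream' line")
  r$axes <- bitmask_decode(r$flags)
  r$slice_dims <- slice_dims_of(r$dims, r$axes)
  r$slice_len <- prod(r$slice_dims)
  r$n_slices <- slice_count(r$dims, r$axes)
  r$next_index <- 0L
  r$closed <- FALSE
  if (!r$binary) {
    if (is.null(r$shared_path) || !file.exists(r$shared_path))
      stop("shared-storage stream names no accessible shared file")
    r$shared_con <- file(r$shared_path, "rb")
  }
  class(r) <- "mdstream_reader"
  r
}

#' Read the next slice from a stream
#'
#' Blocks until the next slice is complete.  Returns `NULL` at a clean end
#' of stream.
#'
#' @param reader handle from [open_stream_reader()].
#' @return `NULL`, or a list with `index` (serial number), `data` (complex
#'   array shaped like one slice) and `meta` (named character vector).
#' @export
read_slice <- function(reader) {
  line <- read_line_raw(reader$con)
  if (is.null(line)) return(NULL)
  parts <- strsplit(line, "\\s+")[[1]]
  if (length(parts) != 4 || parts[1] != "slice")
    stop("protocol error: unexpected message '", line, "'")
  index <- as.numeric(parts[2])
  nbytes <- as.numeric(parts[3])
  nmeta <- as.integer(parts[4])
  if (index != reader$next_index)
    stop("protocol error: slice index ", index, " arrived, expected ",
         reader$next_index)
  meta <- character(0)
  if (nmeta > 0) {
    for (i in seq_len(nmeta)) {
      kv <- read_line_raw(reader$con)
      if (is.null(kv)) stop("truncated stream inside per-slice metadata")
      key <- sub("=.*$", "", kv)
      meta[key] <- sub("^[^=]*=", "", kv)
    }
  }
  n <- reader$slice_len
  if (reader$binary) {
    if (nbytes != 8 * n)
      stop("protocol error: payload of ", nbytes, " bytes, expected ", 8 * n)
    v <- readBin(reader$con, "double", n = 2 * n, size = 4L, endian = "little")
    while (length(v) < 2 * n) {
      more <- readBin(reader$con, "double", n = 2 * n - length(v), size = 4L,
                      endian = "little")
      if (length(more) == 0)
        stop("truncated stream: payload shorter than promised")
      v <- c(v, more)
    }
  } else {
    seek(reader$shared_con, where = index * 8 * n, rw = "read")
    v <- readBin(reader$shared_con, "double", n = 2 * n, size = 4L,
                 endian = "little")
    if (length(v) < 2 * n)
      stop("truncated shared-storage region")
  }
  data <- array(complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)]),
                dim = reader$slice_dims)
  reader$next_index <- reader$next_index + 1L
  list(index = index, data = data, meta = meta)
}

#' Capture a stream into a cfl file pair
#'
#' Reads a whole stream and stores the reassembled array as `.cfl`/`.hdr`.
#'
#' @param source stream source, see [open_stream_reader()].
#' @param path output path for [write_cfl()].
#' @return the array, invisibly.
#' @export
stream_to_file <- function(source, path) {
  x <- collect_stream(source)
  write_cfl(path, x)
  invisible(x)
}

#' Read a whole stream into memory
#'
#' @param source stream source, see [open_stream_reader()].
#' @return the reassembled complex array (trailing unit dimensions dropped).
#' @export
collect_stream <- function(source) {
  r <- open_stream_reader(source)
  on.exit(close_stream(r))
  rank <- max(which(r$dims > 1L), 1L)
  x <- array(0 + 0i, dim = r$dims[seq_len(rank)])
  dims16 <- r$dims
  repeat {
    s <- read_slice(r)
    if (is.null(s)) break
    x[slice_linear_indices(dims16, r$axes, s$index)] <- s$data
  }
  x
}

#' Send a cfl file or in-memory array as a stream
#'
#' @param x a complex array, or a path readable by [read_cfl()].
#' @param sink stream sink, see [open_stream_writer()].
#' @param flags bitmask of the axes to stream over.
#' @param binary inline-binary mode, see [open_stream_writer()].
#' @param delay seconds to wait before emitting each slice (emulates
#'   per-slice acquisition time); default 0.
#' @return invisibly, the number of slices written.
#' @export
file_to_stream <- function(x, sink, flags, binary = FALSE, delay = 0) {
  if (is.character(x)) x <- read_cfl(x)
  if (delay < 0) stop("delay must be >= 0")
  w <- open_stream_writer(sink, md_dims(x), flags, binary = binary)
  on.exit(close_stream(w))
  for (s in seq_len(w$n_slices)) {
    if (delay > 0) Sys.sleep(delay)
    write_slice(w, extract_slice(x, w$axes, s - 1L))
  }
  invisible(w$n_slices)
}
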