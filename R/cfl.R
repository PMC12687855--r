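# cfl/hdr file pairs: .hdr is an ASCII header ("# Dimensions" plus a line of
# 16 extents), .cfl is raw little-endian complex single precision in
# column-major order (first axis fastest, real then imaginary per value).

cfl_paths <- function(path) {
  base <- sub("\\.(cfl|hdr)$", "", path)
  list(hdr = paste0(base, ".hdr"), cfl = paste0(base, ".cfl"))
}

cfl_header_text <- function(dims) {
  dims <- md_check_dims(dims)
  dims <- c(dims, rep(1L, max(0L, MD_MAX_DIMS - length(dims))))
  paste0("# Dimensions\n", paste(dims, collapse = " "), "\n")
}

#' Write an array as a cfl/hdr file pair
#'
#' @param path file path; a `.cfl`/`.hdr` extension is stripped and both
#'   files are written next to each other.
#' @param x complex array.
#' @return `path`, invisibly.
#' @seealso [read_cfl()]
#' @export
write_cfl <- function(path, x) {
  p <- cfl_paths(path)
  dims <- md_dims(x)
  writeChar(cfl_header_text(dims), p$hdr, eos = NULL)
  con <- file(p$cfl, "wb")
  on.exit(close(con))
  writeBin(c(rbind(Re(x), Im(x))), con, size = 4L, endian = "little")
  invisible(path)
}

parse_cfl_header <- function(lines) {
  if (length(lines) < 2 || !grepl("^# Dimensions", lines[1]))
    stop("malformed header: expected '# Dimensions' on the first line")
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]]))
  if (any(is.na(dims)) || length(dims) < 1)
    stop("malformed header: could not parse extents")
  md_check_dims(dims)
}

#' Read a cfl/hdr file pair
#'
#' @param path file path (with or without extension).
#' @param trim drop trailing extent-1 dimensions (the semantic rank is kept;
#'   rank-0/1 data comes back as a vector-like 1-d array).  Default `TRUE`.
#' @return complex array.
#' @export
read_cfl <- function(path, trim = TRUE) {
  p <- cfl_paths(path)
  if (!file.exists(p$hdr)) stop("header file not found: ", p$hdr)
  if (!file.exists(p$cfl)) stop("data file not found: ", p$cfl)
  dims <- parse_cfl_header(readLines(p$hdr))
  n <- prod(dims)
  expect_bytes <- n * 8
  if (file.size(p$cfl) != expect_bytes)
    stop("size mismatch: header promises ", expect_bytes, " bytes, file has ",
         file.size(p$cfl))
  con <- file(p$cfl, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = 2 * n, size = 4L, endian = "little")
  if (length(v) != 2 * n) stop("truncated cfl file: ", p$cfl)
  x <- complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
  if (trim) {
    rank <- max(which(dims > 1L), 1L)
    dims <- dims[seq_len(rank)]
  }
  array(x, dim = dims)
}
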