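# Loop driver: apply a tool to every slice of its inputs, over ranges,
# optionally in parallel workers, and directly on live streams.

.mdstream_tools <- new.env(parent = emptyenv())

#' Register a tool with the loop driver
#'
#' A plain tool is a function `function(inputs, opts)` mapping a list of
#' input slices to one output slice.  A stream-aware tool additionally
#' threads state: `function(state, inputs, opts)` returning
#' `list(state = ..., output = ...)`, so it can use information from
#' previously processed slices (e.g. temporal filters, RT-NLINV).
#'
#' @param name tool name.
#' @param fun tool function.
#' @param stream_aware whether `fun` has the stateful signature.
#' @export
register_tool <- function(name, fun, stream_aware = FALSE) {
  assign(name, list(fun = fun, stream_aware = stream_aware),
         envir = .mdstream_tools)
  invisible(name)
}

#' Look up a registered tool
#'
#' @param tool a tool name or a function (returned as a plain tool).
#' @return list with `fun` and `stream_aware`.
#' @export
get_tool <- function(tool) {
  if (is.function(tool)) return(list(fun = tool, stream_aware = FALSE))
  if (!exists(tool, envir = .mdstream_tools))
    stop("unknown tool: ", tool)
  get(tool, envir = .mdstream_tools)
}

# Decide per input whether it is sliced or broadcast, checking extents on the
# looped axes against the reference.
classify_inputs <- function(inputs, axes, ref_ext) {
  lapply(inputs, function(x) {
    d <- md_dims(x)
    ext <- d[axes + 1L]
    if (all(ext == ref_ext)) return("slice")
    if (all(ext == 1L)) return("broadcast")
    bad <- axes[which(ext != ref_ext & ext != 1L)[1]]
    stop("shape mismatch on looped axis ", bad, ": input extent ",
         d[bad + 1L], ", reference extent ", ref_ext[which(axes == bad)])
  })
}

slice_inputs <- function(inputs, roles, axes, serial) {
  mapply(function(x, role) {
    if (role == "broadcast") x else extract_slice(x, axes, serial)
  }, inputs, roles, SIMPLIFY = FALSE)
}

#' Apply a tool to every slice of its inputs
#'
#' The slice dimensions are selected by `loop_flags`.  Inputs whose extent is
#' 1 on every looped axis are broadcast unchanged to each invocation (used
#' e.g. for a trajectory shared across frames).  With `workers > 1` slices
#' are computed in parallel but assembled in serial order, so results are
#' identical to the serial run.
#'
#' @param tool tool name (see [register_tool()]) or a function
#'   `function(inputs, opts)`.
#' @param inputs list of complex arrays (a single array is accepted).
#' @param loop_flags bitmask of the looped axes.
#' @param opts options passed to the tool.
#' @param ref_dims extents of the full md-array; defaults to the dimensions
#'   of the first sliced input.  Entries of `end` override extents on the
#'   looped axes.
#' @param start first serial index to process (default 0).
#' @param end exclusive last serial index, or `NULL` for all slices.
#' @param workers number of parallel workers (forked; default 1).
#' @return the assembled output array; slices outside `[start, end)` are
#'   zero.
#' @export
run_looped <- function(tool, inputs, loop_flags, opts = list(),
                       ref_dims = NULL, start = 0, end = NULL, workers = 1) {
  t <- get_tool(tool)
  if (!is.list(inputs)) inputs <- list(inputs)
  axes <- bitmask_decode(loop_flags)
  if (is.null(ref_dims)) {
    ref_dims <- NULL
    for (x in inputs) {
      d <- md_dims(x)
      if (any(d[axes + 1L] > 1L)) { ref_dims <- d; break }
    }
    if (is.null(ref_dims)) ref_dims <- md_dims(inputs[[1]])
  } else {
    ref_dims <- c(md_check_dims(ref_dims),
                  rep(1L, MD_MAX_DIMS - length(ref_dims)))
  }
  ref_ext <- ref_dims[axes + 1L]
  roles <- classify_inputs(inputs, axes, ref_ext)
  n_slices <- prod(ref_ext)
  if (is.null(end)) end <- n_slices
  if (start < 0 || start >= end || end > n_slices)
    stop("invalid slice range [", start, ", ", end, ") for ", n_slices,
         " slices")
  serials <- seq.int(start, end - 1L)
  run_one <- function(s) t$fun(slice_inputs(inputs, roles, axes, s), opts)
  results <- if (workers > 1) {
    parallel::mclapply(serials, run_one, mc.cores = workers)
  } else {
    lapply(serials, run_one)
  }
  out_slice_dims <- md_dims(results[[1]])
  out_dims <- out_slice_dims
  out_dims[axes + 1L] <- ref_ext
  rank <- max(which(out_dims > 1L), 1L)
  out <- array(0 + 0i, dim = out_dims[seq_len(rank)])
  for (i in seq_along(serials))
    out[slice_linear_indices(out_dims, axes, serials[i])] <- results[[i]]
  out
}

#' Apply a tool to a stream, slice by slice
#'
#' The stream flags of the input are used directly as loop flags and the
#' tool runs on every slice as soon as it is received, so the first output
#' slice is emitted long before the input stream ends.  At most
#' `workers` slice buffers are held at any time; the observed peak is
#' reported in the result's `"stats"` attribute.
#'
#' @param tool tool name or function; stream-aware tools (see
#'   [register_tool()]) have their state threaded through the slices.
#' @param source input stream (see [open_stream_reader()]).
#' @param sink output stream sink, or `NULL` to assemble the result in
#'   memory.
#' @param opts options passed to the tool.
#' @param extra_inputs list of broadcast side inputs passed to every
#'   invocation after the streamed slice.
#' @param workers parallel workers for plain tools (stream-aware tools are
#'   inherently serial).
#' @param binary binary mode for the output stream.
#' @return the assembled array (if `sink` is `NULL`) or invisibly the
#'   number of slices; either carries a `"stats"` attribute with
#'   `peak_buffers` and `n_slices`.
#' @export
run_looped_streamed <- function(tool, source, sink = NULL, opts = list(),
                                extra_inputs = list(), workers = 1,
                                binary = FALSE) {
  t <- get_tool(tool)
  if (t$stream_aware) workers <- 1
  r <- open_stream_reader(source)
  on.exit(close_stream(r), add = TRUE)
  axes <- r$axes
  live <- 0L; peak <- 0L
  writer <- NULL
  out <- NULL
  out_dims <- NULL
  state <- NULL
  n_done <- 0L
  finished <- FALSE
  while (!finished) {
    batch <- list()
    while (length(batch) < max(1L, workers)) {
      s <- read_slice(r)
      if (is.null(s)) { finished <- TRUE; break }
      batch[[length(batch) + 1L]] <- s
      live <- live + 1L
      peak <- max(peak, live)
    }
    if (length(batch) == 0) break
    results <- if (t$stream_aware) {
      lapply(batch, function(s) {
        res <- t$fun(state, c(list(s$data), extra_inputs), opts)
        state <<- res$state
        res$output
      })
    } else if (workers > 1 && length(batch) > 1) {
      parallel::mclapply(batch, function(s)
        t$fun(c(list(s$data), extra_inputs), opts), mc.cores = workers)
    } else {
      lapply(batch, function(s) t$fun(c(list(s$data), extra_inputs), opts))
    }
    for (i in seq_along(batch)) {
      res <- results[[i]]
      if (is.null(out_dims)) {
        out_dims <- md_dims(res)
        out_dims[axes + 1L] <- r$dims[axes + 1L]
        if (!is.null(sink)) {
          writer <- open_stream_writer(sink, out_dims, r$flags, binary = binary)
        } else {
          rank <- max(which(out_dims > 1L), 1L)
          out <- array(0 + 0i, dim = out_dims[seq_len(rank)])
        }
      }
      if (!is.null(writer)) {
        write_slice(writer, res)
      } else {
        out[slice_linear_indices(out_dims, axes, batch[[i]]$index)] <- res
      }
      live <- live - 1L
      n_done <- n_done + 1L
    }
  }
  if (!is.null(writer)) close_stream(writer)
  stats <- list(peak_buffers = peak, n_slices = n_done)
  if (is.null(sink)) {
    attr(out, "stats") <- stats
    out
  } else {
    structure(invisible(n_done), stats = stats)
  }
}

#' Copy an array, optionally as a stream with per-slice delay
#'
#' With a `sink`, the array is emitted as a stream over the axes in
#' `flags`, each slice no earlier than `delay` seconds after the previous
#' one — emulating per-slice acquisition time of a measurement.
#'
#' @param x complex array (or cfl path).
#' @param sink stream sink, or `NULL` to return the copy.
#' @param flags streamed axes (required with a sink).
#' @param delay seconds per slice, `>= 0`.
#' @param binary inline-binary stream mode.
#' @return the array (no sink) or invisibly the slice count.
#' @export
md_copy <- function(x, sink = NULL, flags = NULL, delay = 0, binary = FALSE) {
  if (delay < 0) stop("delay must be >= 0")
  if (is.character(x)) x <- read_cfl(x)
  if (is.null(sink)) return(x)
  if (is.null(flags)) stop("flags are required when streaming")
  file_to_stream(x, sink, flags, binary = binary, delay = delay)
}
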