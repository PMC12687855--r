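# Reconstruction pipelines: configuration, stage graph construction, an
# in-memory streamed executor with per-frame instrumentation, a
# multi-process executor for linear per-frame chains, and DOT graph
# tracing.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruction pipeline configuration
#'
#' Three canonical configurations mirror common real-time setups:
#' a lightweight gridding reconstruction with view-sharing and few virtual
#' coils; an RT-NLINV reconstruction with gradient-delay correction; and a
#' high-quality RT-NLINV with aligned dynamic coil compression, NLM filter
#' and more iterations (see [pipeline_presets()]).
#'
#' @param recon `"grid"` (Ram-Lak + adjoint NUFFT + RSS) or `"nlinv"`.
#' @param view_sharing reconstruct each frame from the union of the last
#'   `turns` frames' spokes (gridding only).
#' @param n_virtual_coils virtual coils for compression (`0` disables).
#' @param cc_mode compression matrix update strategy, see [cc_stream()].
#' @param delay_correction estimate and correct gradient delays per frame.
#' @param median_window temporal median window (0 = off, else odd).
#' @param nlm apply the frame-wise non-local means filter.
#' @param nlinv_iterations Gauss-Newton steps for `recon = "nlinv"`.
#' @param trajectory `"turn-based"` or `"golden-rational"`.
#' @param instrumentation collect per-frame timestamps.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(recon = c("grid", "nlinv"), view_sharing = FALSE,
                            n_virtual_coils = 0,
                            cc_mode = c("static", "dynamic-unaligned",
                                        "dynamic-aligned"),
                            delay_correction = FALSE, median_window = 0,
                            nlm = FALSE, nlinv_iterations = 6,
                            trajectory = c("turn-based", "golden-rational"),
                            instrumentation = TRUE) {
  recon <- match.arg(recon)
  cc_mode <- match.arg(cc_mode)
  trajectory <- match.arg(trajectory)
  if (view_sharing && recon != "grid")
    stop("view sharing is only supported with the gridding reconstruction")
  if (median_window != 0 && median_window %% 2 == 0)
    stop("median window must be odd (or 0)")
  structure(list(recon = recon, view_sharing = view_sharing,
                 n_virtual_coils = n_virtual_coils, cc_mode = cc_mode,
                 delay_correction = delay_correction,
                 median_window = median_window, nlm = nlm,
                 nlinv_iterations = nlinv_iterations,
                 trajectory = trajectory,
                 instrumentation = instrumentation),
            class = "pipeline_config")
}

#' Canonical pipeline configurations
#'
#' `1`: lightweight gridding + view-sharing, 4 virtual coils, static
#' compression, no delay correction.  `2`: RT-NLINV with delay correction,
#' no NLM, no dynamic compression (the latency-measurement setup).
#' `3`: RT-NLINV with aligned dynamic compression, NLM and more
#' iterations (highest quality).
#'
#' @param which 1, 2 or 3.
#' @return a [pipeline_config()].
#' @export
pipeline_presets <- function(which) {
  switch(as.character(which),
    "1" = pipeline_config(recon = "grid", view_sharing = TRUE,
                          n_virtual_coils = 4, cc_mode = "static",
                          median_window = 5),
    "2" = pipeline_config(recon = "nlinv", delay_correction = TRUE,
                          median_window = 5),
    "3" = pipeline_config(recon = "nlinv", delay_correction = TRUE,
                          n_virtual_coils = 4, cc_mode = "dynamic-aligned",
                          nlm = TRUE, nlinv_iterations = 8,
                          median_window = 5),
    stop("unknown preset ", which))
}

#' Build the stage graph of a pipeline
#'
#' @param config a [pipeline_config()].
#' @param grid reconstruction matrix size (trajectory band `+/- grid/2`).
#' @param turns turns of the turn-based pattern (for view sharing).
#' @return object of class `md_pipeline` with a `stages` character vector
#'   (in execution order) and the closures run by [run_pipeline()].
#' @export
build_pipeline <- function(config, grid, turns = 5) {
  stages <- character(0)
  if (config$delay_correction) stages <- c(stages, "ring", "trajcor")
  if (config$n_virtual_coils > 0) stages <- c(stages, "tee", "cc", "ccapply")
  if (config$view_sharing) stages <- c(stages, "viewshare")
  stages <- c(stages,
              if (config$recon == "grid") c("ramlak", "nufft", "rss")
              else "nlinv",
              "resize")
  if (config$median_window > 0) stages <- c(stages, "median")
  if (config$nlm) stages <- c(stages, "nlm")
  structure(list(config = config, grid = grid, turns = turns,
                 stages = stages),
            class = "md_pipeline")
}

#' @export
print.md_pipeline <- function(x, ...) {
  cat("pipeline:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' DOT graph description of a pipeline
#'
#' Emits the stage graph in the DOT graph description language: stages are
#' nodes, pipes are edges; the input FIFOs (`ksp.fifo`, `trj.fifo`) and
#' the output FIFO (`img.fifo`) appear as box nodes, and the coil
#' compression split is drawn through its `tee` node.
#'
#' @param pipeline an `md_pipeline`.
#' @return a single string of DOT source.
#' @export
trace_graph <- function(pipeline) {
  st <- pipeline$stages
  lines <- c("digraph pipeline {",
             "  rankdir=LR;",
             "  \"ksp.fifo\" [shape=box];",
             "  \"trj.fifo\" [shape=box];",
             "  \"img.fifo\" [shape=box];")
  for (s in st) lines <- c(lines, sprintf("  \"%s\" [shape=ellipse];", s))
  first_data <- setdiff(st, c("cc", "trajcor"))[1]
  lines <- c(lines, sprintf("  \"ksp.fifo\" -> \"%s\";",
                            if ("tee" %in% st) "tee" else first_data))
  if ("ring" %in% st) {
    lines <- c(lines,
               "  \"ksp.fifo\" -> \"ring\";",
               "  \"trj.fifo\" -> \"ring\";",
               "  \"ring\" -> \"trajcor\";",
               "  \"trj.fifo\" -> \"trajcor\";")
    traj_src <- "trajcor"
  } else {
    traj_src <- "trj.fifo"
  }
  if ("tee" %in% st) {
    lines <- c(lines, "  \"tee\" -> \"cc\";", "  \"tee\" -> \"ccapply\";",
               "  \"cc\" -> \"ccapply\";")
  }
  chain <- setdiff(st, c("ring", "trajcor", "tee", "cc"))
  for (i in seq_along(chain)[-1])
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", chain[i - 1], chain[i]))
  recon_node <- if (pipeline$config$recon == "grid") "nufft" else "nlinv"
  lines <- c(lines, sprintf("  \"%s\" -> \"%s\";", traj_src, recon_node))
  lines <- c(lines, sprintf("  \"%s\" -> \"img.fifo\";", chain[length(chain)]))
  paste(c(lines, "}"), collapse = "\n")
}

#' Run a pipeline on a frame series
#'
#' In-memory streamed execution: frames pass through the stage chain one
#' by one, stream-aware stages (coil compression, RT-NLINV state, median
#' filter, view sharing) thread their state, so frame `t` depends only on
#' frames `<= t`.  With instrumentation enabled, per-frame timestamps are
#' taken after preprocessing, reconstruction and post-processing.
#'
#' @param pipeline an `md_pipeline` from [build_pipeline()].
#' @param ksp k-space array `(read, spoke, coil, frame)`, or a stream
#'   source (FIFO path, `"-"`, captured file) carrying frames on axis 3 —
#'   frames are then processed as they arrive, so a live producer (e.g.
#'   [md_copy()] with a delay, running in another process) overlaps its
#'   acquisition with the reconstruction.
#' @param trj trajectory array `(3, read, spoke, frame)`.
#' @param frame_arrival optional vector of arrival timestamps (seconds);
#'   defaults to the actual processing clock.
#' @return list with `images` (`(grid, grid, 1, frames)` real magnitudes),
#'   `timings` (a [frame_timings()] data.frame or `NULL`), `delays`
#'   (per-frame [delay_matrix()] list if delay correction ran) and
#'   `cc_matrices`.
#' @export
run_pipeline <- function(pipeline, ksp, trj, frame_arrival = NULL) {
  config <- pipeline$config
  N <- pipeline$grid
  reader <- NULL
  if (!is.array(ksp)) {
    reader <- open_stream_reader(ksp)
    on.exit(close_stream(reader), add = TRUE)
    nf <- reader$n_slices
  } else {
    nf <- dim(ksp)[4]
  }
  images <- array(0, dim = c(N, N, 1, nf))
  delays <- if (config$delay_correction) vector("list", nf) else NULL
  cc_mats <- if (config$n_virtual_coils > 0) vector("list", nf) else NULL
  median_state <- NULL
  nlinv_state <- NULL
  cc_prev <- NULL
  vs_buf <- list()
  t_arr <- t_pre <- t_rec <- t_post <- numeric(nf)
  clock <- function() proc.time()[["elapsed"]]
  for (f in seq_len(nf)) {
    if (is.null(reader)) {
      frame_ksp <- array(ksp[, , , f], dim = dim(ksp)[1:3])
    } else {
      s <- read_slice(reader)
      if (is.null(s)) { nf <- f - 1L; break }
      frame_ksp <- array(s$data, dim = reader$dims[1:3])
    }
    frame_trj <- array(trj[, , , f], dim = dim(trj)[1:3])
    t_arr[f] <- if (is.null(frame_arrival)) clock() else frame_arrival[f]

    # --- preprocessing ---
    if (config$delay_correction) {
      S <- estimate_delay(frame_ksp, frame_trj)
      delays[[f]] <- S
      frame_trj <- correct_trajectory(frame_trj, S)
    }
    if (config$n_virtual_coils > 0) {
      m <- if (config$cc_mode == "static") {
        if (f == 1) cc_svd(frame_ksp, config$n_virtual_coils) else cc_mats[[1]]
      } else {
        cc_svd(frame_ksp, config$n_virtual_coils)
      }
      if (config$cc_mode == "dynamic-aligned" && !is.null(cc_prev))
        m <- m %*% procrustes_rotation(m, cc_prev)
      cc_mats[[f]] <- m
      cc_prev <- m
      frame_ksp <- ccapply(frame_ksp, m)
    }
    t_pre[f] <- clock()

    # --- reconstruction ---
    if (config$recon == "grid") {
      if (config$view_sharing) {
        vs_buf[[length(vs_buf) + 1L]] <- list(ksp = frame_ksp, trj = frame_trj)
        if (length(vs_buf) > pipeline$turns) vs_buf <- vs_buf[-1]
        use_ksp <- do.call(abind2, lapply(vs_buf, `[[`, "ksp"))
        use_trj <- do.call(abind2_trj, lapply(vs_buf, `[[`, "trj"))
      } else {
        use_ksp <- frame_ksp
        use_trj <- frame_trj
      }
      w <- ramlak_filter(use_ksp, use_trj)
      coil_imgs <- nufft_adjoint(w, use_trj * 2, grid = 2 * N)
      img2 <- rss_combine(coil_imgs, coil_axis = 2)
      img <- resize_center(img2, c(N, N))[, , 1]
    } else {
      cfg <- nlinv_config(iterations = config$nlinv_iterations)
      res <- nlinv_frame(frame_ksp, frame_trj, grid = N, config = cfg,
                         state = nlinv_state)
      nlinv_state <- res$state
      img <- res$image
    }
    t_rec[f] <- clock()

    # --- post-processing ---
    img <- Mod(img)
    if (config$median_window > 0) {
      stp <- median_tool_step(median_state, list(img),
                              list(L = config$median_window))
      median_state <- stp$state
      img <- Re(stp$output)
    }
    if (config$nlm) img <- nlm_filter(img)
    images[, , 1, f] <- img
    t_post[f] <- clock()
  }
  timings <- if (config$instrumentation) {
    frame_timings(seq_len(nf), t_arr, t_pre, t_rec, t_post)
  } else NULL
  list(images = images, timings = timings, delays = delays,
       cc_matrices = cc_mats)
}

# concatenate frames along the spoke axis
abind2 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  nsp <- sum(vapply(parts, function(p) dim(p)[2], numeric(1)))
  out <- array(0 + 0i, dim = c(d[1], nsp, d[3]))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[2]
    out[, at + seq_len(k), ] <- p
    at <- at + k
  }
  out
}

abind2_trj <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  nsp <- sum(vapply(parts, function(p) dim(p)[3], numeric(1)))
  out <- array(0 + 0i, dim = c(d[1], d[2], nsp))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[3]
    out[, , at + seq_len(k)] <- p
    at <- at + k
  }
  out
}

#' Simulate, reconstruct and time a full demonstration run
#'
#' Generates a synthetic radial FLASH acquisition, runs it through the
#' configured pipeline and reports images, per-frame timings and the
#' reconstruction error against the simulated ground truth.
#'
#' @param seed RNG seed for the simulation.
#' @param config a [pipeline_config()].
#' @param n_frames number of frames.
#' @param matrix matrix size (test scale 64 by default).
#' @param n_coils physical coils.
#' @param noise_sigma simulator noise level.
#' @param delay injected [delay_matrix()] (or `NULL`).
#' @param motion_amplitude phantom motion amplitude in pixels.
#' @return list with `images`, `timings`, `nrmse` (per frame), `sim`.
#' @export
run_demo <- function(seed, config, n_frames = 10, matrix = 64, n_coils = 8,
                     noise_sigma = 0, delay = NULL, motion_amplitude = 0) {
  params <- seq_params(matrix = matrix, adc_samples = 2 * matrix)
  scene <- phantom_scene(params, n_coils = n_coils,
                         motion_amplitude = motion_amplitude)
  trj <- if (config$trajectory == "turn-based") {
    traj_turn_based(params, n_frames)
  } else {
    traj_golden_rational(params, n_frames = n_frames)
  }
  sim <- simulate_kspace(scene, trj, delay = delay,
                         noise_sigma = noise_sigma, seed = seed)
  pl <- build_pipeline(config, grid = matrix, turns = params$turns)
  out <- run_pipeline(pl, sim$ksp, sim$trj)
  err <- vapply(seq_len(n_frames), function(f)
    nrmse(out$images[, , 1, f], sim$truth[, , 1, f]), numeric(1))
  c(out, list(nrmse = err, sim = sim))
}

#' Producer/consumer copy-then-FFT pipeline over a FIFO
#'
#' Forks a producer that streams the slices of `x` with a per-slice delay
#' (emulating acquisition) into a named FIFO, while the parent consumes
#' them.  In `"pipelined"` mode the FFT runs on every slice as it arrives;
#' in `"blocked"` mode the consumer first collects the whole stream and
#' only then transforms it — so the pipelined variant overlaps waiting and
#' computing.
#'
#' @param x complex array, slices along the last axis.
#' @param delay producer delay per slice in seconds.
#' @param mode `"pipelined"` or `"blocked"`.
#' @param fft_flags axes bitmask for the per-slice FFT (default 3).
#' @return list with `result` (transformed array) and `elapsed` (seconds).
#' @export
pipeline_copy_fft <- function(x, delay, mode = c("pipelined", "blocked"),
                              fft_flags = 3) {
  mode <- match.arg(mode)
  nd <- length(dim(x))
  loop_flags <- bitmask_encode(nd - 1)
  fifo_path <- tempfile(fileext = ".fifo")
  ensure_fifo(fifo_path)
  on.exit(unlink(fifo_path), add = TRUE)
  t0 <- proc.time()[["elapsed"]]
  job <- parallel::mcparallel(
    md_copy(x, sink = fifo_path, flags = loop_flags, delay = delay,
            binary = TRUE))
  result <- if (mode == "pipelined") {
    run_looped_streamed(function(inputs, opts)
      fft_md(inputs[[1]], fft_flags, inverse = TRUE), fifo_path)
  } else {
    whole <- collect_stream(fifo_path)
    fft_md(whole, fft_flags, inverse = TRUE)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  parallel::mccollect(job)
  list(result = result, elapsed = elapsed)
}
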