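# Latency instrumentation: per-frame stage timestamps, steady-state
# extraction, and lag estimation between movement curves.

#' Assemble per-frame timing records
#'
#' @param frame integer frame indices.
#' @param t_last_spoke,t_preproc_done,t_recon_done,t_postproc_done
#'   timestamps in seconds (monotonic clock); must be non-decreasing in
#'   this order within each frame.
#' @return data.frame of class `frame_timings`.
#' @export
frame_timings <- function(frame, t_last_spoke, t_preproc_done,
                          t_recon_done, t_postproc_done) {
  df <- data.frame(frame = frame, t_last_spoke = t_last_spoke,
                   t_preproc_done = t_preproc_done,
                   t_recon_done = t_recon_done,
                   t_postproc_done = t_postproc_done)
  bad <- with(df, t_preproc_done < t_last_spoke |
                  t_recon_done < t_preproc_done |
                  t_postproc_done < t_recon_done)
  if (any(is.na(bad)))
    stop("instrumentation error: missing timestamp in frame(s) ",
         paste(df$frame[is.na(bad)], collapse = ", "))
  if (any(bad))
    stop("instrumentation error: non-monotonic timestamps in frame(s) ",
         paste(df$frame[bad], collapse = ", "))
  class(df) <- c("frame_timings", "data.frame")
  df
}

#' Summarize per-stage durations and total latency
#'
#' Per-frame latency is the time from arrival of the last spoke to
#' transmission of the post-processed frame; stage durations are the
#' differences of consecutive timestamps.  Steady-state statistics exclude
#' the warm-up detected by [steady_state()].
#'
#' @param timings a [frame_timings()] data.frame.
#' @return list with `per_frame` (data.frame of stage durations and total
#'   latency) and `steady` (the [steady_state()] result for the total
#'   latency).
#' @export
summarize_timings <- function(timings) {
  per <- data.frame(
    frame = timings$frame,
    preproc = timings$t_preproc_done - timings$t_last_spoke,
    recon = timings$t_recon_done - timings$t_preproc_done,
    postproc = timings$t_postproc_done - timings$t_recon_done)
  per$latency <- per$preproc + per$recon + per$postproc
  st <- steady_state(per$latency)
  stage_stats <- vapply(per[, c("preproc", "recon", "postproc", "latency")],
                        function(v) {
                          keep <- if (is.na(st$warmup)) v
                                  else v[seq_along(v) > st$warmup]
                          c(mean = mean(keep), sd = stats::sd(keep))
                        }, numeric(2))
  list(per_frame = per, steady = st, stage_stats = t(stage_stats))
}

#' Detect the steady state of a latency series
#'
#' After pipeline start-up the reconstruction catches up with the
#' acquisition and the per-frame latency decays onto a plateau.  The
#' warm-up is the shortest prefix after which the moving-average slope
#' stays below a threshold; the steady latency is reported as mean and sd
#' of the remainder.
#'
#' @param series numeric latency series (length >= 5).
#' @param window moving-average window (default 5).
#' @param slope_frac slope threshold as a fraction of the series mean per
#'   frame (default 0.02).
#' @return list with `warmup` (number of excluded frames, `NA` if no
#'   steady region exists), `mean`, `sd`, and `steady` (logical).
#' @export
steady_state <- function(series, window = 5, slope_frac = 0.02) {
  n <- length(series)
  if (n < 5) stop("series too short (need >= 5 frames)")
  ma <- stats::filter(series, rep(1 / window, window), sides = 1)
  slope <- diff(ma)
  slope <- slope[!is.na(slope)]
  thresh <- slope_frac * mean(abs(series))
  ok <- abs(slope) <= thresh
  # shortest prefix after which the slope magnitude stays small
  warmup <- NA_integer_
  for (w in 0:(length(ok) - 1)) {
    if (all(ok[(w + 1):length(ok)])) { warmup <- w; break }
  }
  if (is.na(warmup) || warmup >= n - 1)
    return(list(warmup = NA_integer_, mean = NA_real_, sd = NA_real_,
                steady = FALSE))
  keep <- series[(warmup + 1):n]
  list(warmup = warmup, mean = mean(keep), sd = stats::sd(keep),
       steady = TRUE)
}

#' Lag between two movement curves by cross-correlation
#'
#' Finds the lag maximizing the normalized cross-correlation of the two
#' (equally sampled) curves and refines it to sub-sample precision by
#' parabolic interpolation around the peak.  A positive result means
#' `b` lags `a`.
#'
#' @param a,b numeric curves of equal length (>= 8).
#' @param sample_rate samples per second (default 1: result in samples).
#' @param max_lag largest absolute lag searched, in samples (default:
#'   half the curve length).
#' @return lag in seconds (samples if `sample_rate = 1`).
#' @export
crosscorr_delay <- function(a, b, sample_rate = 1, max_lag = NULL) {
  n <- length(a)
  if (length(b) != n) stop("curves must have equal length")
  if (n < 8) stop("curves too short (need >= 8 samples)")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined delay: a curve has zero variance")
  if (is.null(max_lag)) max_lag <- n %/% 2
  a <- (a - mean(a)) / stats::sd(a)
  b <- (b - mean(b)) / stats::sd(b)
  lags <- -max_lag:max_lag
  # zero-padded correlation sums: by Cauchy-Schwarz the self-correlation
  # peaks exactly at lag zero (a per-lag mean would bias the peak)
  cc <- vapply(lags, function(l) {
    ia <- seq_len(n)
    ib <- ia + l
    ok <- ib >= 1 & ib <= n
    if (sum(ok) < 4) return(-Inf)
    sum(a[ia[ok]] * b[ib[ok]])
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i]
  if (i > 1 && i < length(lags) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0)
      lag <- lag + 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  lag / sample_rate
}

#' Read a two-column time/value curve from a text file
#'
#' @param path whitespace- or comma-separated text with columns time and
#'   value.
#' @return data.frame with columns `time`, `value`.
#' @export
read_curve <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("time", "value"),
                          comment.char = "#")
  df
}

#' Write timing records as a tab-separated table
#'
#' @param timings a [frame_timings()] data.frame.
#' @param path output path.
#' @export
write_timings <- function(timings, path) {
  utils::write.table(timings, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
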