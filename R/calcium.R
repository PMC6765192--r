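#' Convert a fluorescence trace to dF/F0
#'
#' Baseline F0 is a low percentile of the trace (default the 20th), either
#' global or rolling. The rolling estimate is a strided windowed percentile
#' (computed every half window and linearly interpolated), an O(n)
#' approximation to the exact rolling percentile that tracks slow drift.
#'
#' @param trace tibble with columns `t` (s, uniform) and `F` (a.u. >= 0),
#'   as from [read_trace()] or [simulate_calcium_trace()].
#' @param baseline_method `"percentile_rolling"` (default) or
#'   `"global_percentile"`.
#' @param p baseline percentile (0-100).
#' @param window_s rolling window length (s).
#' @return numeric dF/F0 series with the baseline in attribute `F0`.
#' @export
delta_f_over_f <- function(trace, baseline_method = c("percentile_rolling",
                                                      "global_percentile"),
                           p = 20, window_s = 30) {
  baseline_method <- match.arg(baseline_method)
  validate_trace(trace$t, trace$F)
  F <- trace$F
  n <- length(F)
  if (baseline_method == "global_percentile") {
    F0 <- rep(as.numeric(quantile(F, p / 100)), n)
  } else {
    dt <- trace$t[2] - trace$t[1]
    w <- max(3L, round(window_s / dt))
    stride <- max(1L, w %/% 2L)
    anchors <- unique(c(seq(1L, n, by = stride), n))
    qa <- vapply(anchors, function(i) {
      lo <- max(1L, i - w %/% 2L); hi <- min(n, i + w %/% 2L)
      as.numeric(quantile(F[lo:hi], p / 100))
    }, 0)
    F0 <- approx(anchors, qa, xout = seq_len(n), rule = 2)$y
  }
  if (any(F0 <= 0)) stop("baseline F0 is not positive")
  structure((F - F0) / F0, F0 = F0)
}

#' Detect spontaneous calcium transients in a dF/F0 series
#'
#' Detection runs on the detrended series: dF/F0 minus its running median
#' over `detrend_window_s` (long relative to a transient, short relative to
#' residual drift), so peak heights are measured against the local
#' baseline. The noise sd is estimated robustly as the scaled median
#' absolute deviation (x 1.4826) of that detrended series, and the default
#' threshold is `4.5 *` noise sd: detection is then invariant to affine
#' rescaling of the raw fluorescence, keeps the per-trace false-positive
#' probability on pure noise at the percent level, and loses essentially no
#' transient of 5 noise-sd or more. Local maxima above threshold closer
#' than `min_separation_s` are merged, keeping the larger.
#'
#' @param dff numeric dF/F0 series.
#' @param dt sampling interval (s).
#' @param min_amp absolute amplitude threshold; default `4.5 *` estimated
#'   noise sd, but never below `min_amp_floor`.
#' @param min_amp_floor absolute floor (dF/F0 units) on the threshold, so
#'   that numerically tiny residuals on noise-free traces (e.g. detrending
#'   remnants of slow drift) are never called transients; 0.02 is an order
#'   of magnitude below a typical calcium-indicator transient.
#' @param min_separation_s minimum peak separation (s).
#' @param detrend_window_s running-median window (s) for local-baseline
#'   removal.
#' @param smooth_window_s running-mean window (s) applied before peak
#'   finding; suppresses noise-induced secondary maxima on transient tails
#'   while barely attenuating a transient peak.
#' @return object of class `transient_set`: `peak_times` (s, strictly
#'   increasing), `peak_amplitudes` (above local baseline), `n`,
#'   `duration_s`, `noise_sd` (of the smoothed, detrended series).
#' @export
detect_transients <- function(dff, dt, min_amp = NULL, min_separation_s = 2,
                              detrend_window_s = 10, smooth_window_s = 0.5,
                              min_amp_floor = 0.02) {
  n <- length(dff)
  stopifnot(n >= 3, dt > 0, min_separation_s >= 0, detrend_window_s > 0)
  k <- max(3L, round(detrend_window_s / dt))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 0L) n - 1L else n)
  det_raw <- dff - runmed(dff, k)
  det <- det_raw
  ks <- max(1L, round(smooth_window_s / dt))
  if (ks > 1) {
    kern <- rep(1 / ks, ks)
    det <- as.numeric(stats::filter(det, kern, sides = 2))
    det[is.na(det)] <- 0
  }
  noise_sd <- mad(det)
  if (is.null(min_amp)) min_amp <- max(4.5 * noise_sd, min_amp_floor)
  core <- det[2:(n - 1)]
  is_peak <- core > det[1:(n - 2)] & core >= det[3:n] & core > min_amp
  idx <- which(is_peak) + 1L
  # prominence gate: a noise bump riding a transient's decay tail rises only
  # noise-high above the surrounding slope and is discarded; a genuine
  # transient rises by about its full amplitude
  if (length(idx) > 1) {
    prom <- vapply(idx, function(p) {
      v <- det[p]
      lmin <- v; i <- p
      while (i > 1 && det[i] <= v) { i <- i - 1L; lmin <- min(lmin, det[i]) }
      lbase <- if (det[i] > v) lmin else min(det[seq_len(p)])
      rmin <- v; i <- p
      while (i < n && det[i] <= v) { i <- i + 1L; rmin <- min(rmin, det[i]) }
      rbase <- if (det[i] > v) rmin else min(det[p:n])
      v - max(lbase, rbase)
    }, 0)
    idx <- idx[prom > min_amp]
  }
  if (length(idx) > 1 && min_separation_s > 0) {
    ord <- idx[order(det[idx], decreasing = TRUE)]
    kept <- integer(0)
    for (i in ord) {
      if (!length(kept) || min(abs(kept - i)) * dt >= min_separation_s)
        kept <- c(kept, i)
    }
    idx <- sort(kept)
  }
  # smoothing delays (never advances) the maximum of a sharp-rise,
  # slow-decay transient; refine each peak to the unsmoothed argmax just
  # before the smoothed one
  if (ks > 1 && length(idx)) {
    idx <- vapply(idx, function(p) {
      lo <- max(1L, p - ks)
      as.integer(lo + which.max(det_raw[lo:p]) - 1L)
    }, 0L)
    idx <- sort(unique(idx))
  }
  structure(list(peak_times = (idx - 1) * dt,
                 peak_amplitudes = det_raw[idx],
                 n = length(idx),
                 duration_s = (n - 1) * dt,
                 noise_sd = noise_sd),
            class = "transient_set")
}

#' @export
print.transient_set <- function(x, ...) {
  cat(sprintf("<transient_set> %d peaks in %.1f s (%.2f events/min), noise sd %.3g\n",
              x$n, x$duration_s, transient_frequency(x), x$noise_sd))
  invisible(x)
}

#' Transient frequency in events per minute
#'
#' `60 * count / duration` by default. Detection cannot resolve two
#' transients closer than its merge window; when estimating an underlying
#' event rate, `dead_time_s` applies the standard non-paralysable dead-time
#' correction `rate/(1 - rate * dead_time)` to the per-second rate.
#'
#' @param ts a [detect_transients()] result.
#' @param duration_s recording duration (s); defaults to the duration stored
#'   in the transient set.
#' @param dead_time_s detector dead time (s); 0 (default) reports the raw
#'   observed frequency, `min_separation_s` corrects for merged pairs.
#' @return events/min.
#' @export
transient_frequency <- function(ts, duration_s = ts$duration_s,
                                dead_time_s = 0) {
  if (duration_s <= 0) stop("duration must be positive")
  r <- ts$n / duration_s
  if (dead_time_s > 0) {
    if (r * dead_time_s >= 1) stop("rate saturates the dead time")
    r <- r / (1 - r * dead_time_s)
  }
  60 * r
}

#' Reduce a single-plane image time series to ROI traces
#'
#' Mean intensity over each ROI mask per frame; ROI discovery itself is out
#' of scope (masks are supplied).
#'
#' @param frames 3-D array `[y, x, frame]`.
#' @param rois named list of logical masks matching the frame shape.
#' @param dt frame interval (s).
#' @return tibble with columns `roi_id`, `t`, `F`.
#' @export
roi_traces <- function(frames, rois, dt) {
  stopifnot(length(dim(frames)) == 3, dt > 0, length(rois) >= 1)
  nf <- dim(frames)[3]
  out <- lapply(names(rois), function(id) {
    m <- rois[[id]]
    stopifnot(all(dim(m) == dim(frames)[1:2]))
    tibble::tibble(roi_id = id, t = (seq_len(nf) - 1) * dt,
                   F = vapply(seq_len(nf),
                              function(k) mean(frames[, , k][m]), 0))
  })
  dplyr::bind_rows(out)
}
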