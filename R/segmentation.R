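#' Assign each trajectory point to the light or dark zone
#'
#' The zone is decided by the signed offset of the point along the divider
#' normal (which points into the dark half). Points exactly on the divider are
#' labelled light: a deterministic tie-break affecting only a measure-zero
#' set of positions.
#'
#' @param traj a [trajectory()].
#' @param well a [well_geometry()].
#' @return character vector, `"light"`/`"dark"`, one label per point.
#' @export
assign_zone <- function(traj, well) {
  off <- divider_offset(well, traj$x, traj$y)
  ifelse(off > 0, "dark", "light")
}

#' Split a trajectory into zone-delimited path segments
#'
#' Maximal runs of a constant zone label, in trajectory order. Segments tile
#' the trajectory: every point belongs to exactly one segment, and
#' consecutive segments alternate zones.
#'
#' @param traj a [trajectory()].
#' @param labels per-point zone labels from [assign_zone()].
#' @return tibble with one row per segment: `zone`, `start`, `end`
#'   (inclusive point indices), `n_points`, `duration` (s).
#' @export
segment_by_zone <- function(traj, labels) {
  if (length(labels) != nrow(traj))
    stop("labels do not align with trajectory")
  r <- rle(labels)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  tibble::tibble(zone = r$values, start = start, end = end,
                 n_points = r$lengths,
                 duration = traj$t[end] - traj$t[start])
}

#' Remove artefact segments below a length percentile
#'
#' Single-frame zone flickers at the divider generate spurious short
#' segments; segments whose point count falls strictly below the given
#' percentile (default the 1st) of the per-recording segment-length
#' distribution are removed. The percentile is the linear-interpolation
#' empirical percentile; the strict `<` comparison means uniform-length
#' inputs lose nothing. Idempotent at a fixed threshold value.
#'
#' @param segments segment tibble from [segment_by_zone()].
#' @param percentile percentile of `n_points` below which segments are
#'   dropped (0-100).
#' @return the kept segments, with the removed ones in attribute `removed`
#'   and the realised threshold in attribute `threshold`.
#' @export
filter_short_segments <- function(segments, percentile = 1) {
  if (nrow(segments) == 0) stop("no segments to filter")
  thr <- as.numeric(quantile(segments$n_points, percentile / 100, type = 7))
  keep <- segments$n_points >= thr
  out <- segments[keep, , drop = FALSE]
  attr(out, "removed") <- segments[!keep, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Count light/dark transitions
#'
#' Number of adjacent label changes in the unfiltered per-point zone
#' sequence; equivalently the number of entries into either region, and one
#' less than the number of unfiltered segments.
#'
#' @param labels per-point zone labels.
#' @return integer count.
#' @export
count_transitions <- function(labels) {
  if (length(labels) < 1) stop("empty label sequence")
  sum(labels[-1] != labels[-length(labels)])
}
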