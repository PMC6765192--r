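#' Construct and validate a swim trajectory
#'
#' A trajectory is the tracked path of one larva in one well: time in seconds
#' (strictly increasing) and well-centred (x, y) positions in mm. Stored as a
#' tibble with columns `t`, `x`, `y` and attributes `larva_id` and `group`.
#'
#' @param t numeric, seconds, strictly increasing, length >= 2.
#' @param x,y numeric, mm, same length as `t`.
#' @param larva_id identifier string.
#' @param group a [treatment_group()] or `NULL`.
#' @param well a [well_geometry()] used to validate that points lie in the
#'   well, or `NULL` to skip the containment check.
#' @param tol_mm containment slack beyond the well radius (tracking jitter).
#' @return a `trajectory` tibble.
#' @export
trajectory <- function(t, x, y, larva_id = "larva", group = NULL,
                       well = NULL, tol_mm = 0.5) {
  if (!(length(t) == length(x) && length(t) == length(y)))
    stop("t, x, y must have equal length")
  if (length(t) < 2) stop("a trajectory needs at least 2 points")
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop(sprintf("non-increasing time at row %d", bad[1] + 1L))
  if (anyNA(t) || anyNA(x) || anyNA(y)) stop("missing values in trajectory")
  if (!is.null(well)) {
    r <- sqrt((x - well$centre[1])^2 + (y - well$centre[2])^2)
    out <- which(r > well$radius + tol_mm)
    if (length(out))
      stop(sprintf("point beyond well radius + tolerance at row %d (r = %.2f mm)",
                   out[1], r[out[1]]))
  }
  out <- tibble::tibble(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y))
  attr(out, "larva_id") <- as.character(larva_id)
  attr(out, "group") <- group
  class(out) <- c("trajectory", class(out))
  out
}

larva_id_of <- function(traj) attr(traj, "larva_id") %||% "larva"
group_of <- function(traj) attr(traj, "group")

#' @export
print.trajectory <- function(x, ...) {
  grp <- attr(x, "group")
  cat(sprintf("<trajectory> %s%s: %d points, %.1f s\n",
              larva_id_of(x),
              if (is.null(grp)) "" else paste0(" [", format(grp), "]"),
              nrow(x), x$t[nrow(x)] - x$t[1]))
  NextMethod()
}
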