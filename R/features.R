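#' Locomotor speed-class thresholds
#'
#' Tracker speed bands: inactive below 3.3 mm/s, low speed from 3.3 up to
#' (but excluding) 6.4 mm/s, high speed at or above 6.4 mm/s. The printed
#' band edges leave (6.3, 6.4) mm/s unassigned at display precision; the
#' bands are implemented as the exhaustive half-open intervals
#' [0, 3.3), [3.3, 6.4), [6.4, Inf).
#'
#' @param inactive_below mm/s, upper edge of the inactive band.
#' @param high_at_or_above mm/s, lower edge of the high-speed band.
#' @return object of class `speed_thresholds`.
#' @export
speed_thresholds <- function(inactive_below = 3.3, high_at_or_above = 6.4) {
  stopifnot(inactive_below > 0, high_at_or_above > inactive_below)
  structure(list(inactive_below = inactive_below,
                 high_at_or_above = high_at_or_above),
            class = "speed_thresholds")
}

#' Instantaneous speeds between consecutive frames
#'
#' Euclidean displacement over elapsed time for each consecutive point pair;
#' the result has one value per inter-frame interval (length n - 1).
#'
#' @param traj a [trajectory()].
#' @return numeric vector of speeds in mm/s.
#' @export
instantaneous_speeds <- function(traj) {
  if (nrow(traj) < 2) stop("need at least 2 points")
  dt <- diff(traj$t)
  if (any(dt == 0)) stop("zero time step")
  sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt
}

#' Classify speeds into locomotor classes
#'
#' @param speeds numeric, mm/s (non-negative).
#' @param th a [speed_thresholds()].
#' @return factor with levels `inactive`, `low`, `high`.
#' @export
classify_speed <- function(speeds, th = speed_thresholds()) {
  if (any(speeds < 0)) stop("negative speed")
  cls <- ifelse(speeds >= th$high_at_or_above, "high",
                ifelse(speeds >= th$inactive_below, "low", "inactive"))
  factor(cls, levels = c("inactive", "low", "high"))
}

#' Time budgets per zone and speed class, in 1-min bins
#'
#' Splits the recording into bins (default 60 s), and per bin computes the
#' percentage of time in the light and, within each zone, the percentage of
#' zone time spent in each locomotor class (normalised to zone time so that
#' light/dark preference differences do not confound activity). Bin values
#' are then averaged with equal weight; bins with zero time in a zone are
#' excluded from that zone's class averages. Optional coarser blocks
#' (e.g. 15 min) average the same bin values within each block.
#'
#' @param traj a [trajectory()].
#' @param labels per-point zone labels ([assign_zone()]).
#' @param classes per-interval speed classes ([classify_speed()]).
#' @param bin_s bin width in seconds.
#' @param block_s optional block width in seconds (a multiple of `bin_s`).
#' @return list with elements `pct_time_light` (scalar), `zones` (tibble:
#'   zone, pct_time, pct_inactive, pct_low, pct_high), `bins` (per-bin
#'   values) and, when `block_s` is given, `blocks`.
#' @export
time_budgets <- function(traj, labels, classes, bin_s = 60, block_s = NULL) {
  n <- nrow(traj)
  if (length(labels) != n) stop("labels do not align with trajectory")
  if (length(classes) != n - 1) stop("classes must have one value per interval")
  dur <- traj$t[n] - traj$t[1]
  if (dur < bin_s) stop("recording shorter than one bin")
  if (!is.null(block_s) && block_s %% bin_s != 0)
    stop("block_s must be a multiple of bin_s")
  iv <- tibble::tibble(
    bin = floor((traj$t[-n] - traj$t[1]) / bin_s) + 1L,
    zone = labels[-n],
    class = as.character(classes),
    dt = diff(traj$t))

  bin_tot <- iv |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(total = sum(.data$dt),
                     light = sum(.data$dt[.data$zone == "light"]),
                     .groups = "drop") |>
    dplyr::mutate(pct_light = 100 * .data$light / .data$total)

  bz <- iv |>
    dplyr::group_by(.data$bin, .data$zone) |>
    dplyr::summarise(
      ztime = sum(.data$dt),
      pct_inactive = 100 * sum(.data$dt[.data$class == "inactive"]) / sum(.data$dt),
      pct_low = 100 * sum(.data$dt[.data$class == "low"]) / sum(.data$dt),
      pct_high = 100 * sum(.data$dt[.data$class == "high"]) / sum(.data$dt),
      .groups = "drop")

  agg_zone <- function(bz_sub, bins_sub) {
    zres <- lapply(c("light", "dark"), function(z) {
      rows <- bz_sub[bz_sub$zone == z, , drop = FALSE]
      pct_time <- if (z == "light") mean(bins_sub$pct_light)
                  else mean(100 - bins_sub$pct_light)
      tibble::tibble(
        zone = z, pct_time = pct_time,
        pct_inactive = if (nrow(rows)) mean(rows$pct_inactive) else NA_real_,
        pct_low = if (nrow(rows)) mean(rows$pct_low) else NA_real_,
        pct_high = if (nrow(rows)) mean(rows$pct_high) else NA_real_)
    })
    dplyr::bind_rows(zres)
  }

  out <- list(pct_time_light = mean(bin_tot$pct_light),
              zones = agg_zone(bz, bin_tot),
              bins = dplyr::left_join(bz, bin_tot[, c("bin", "pct_light")],
                                      by = "bin"))
  if (!is.null(block_s)) {
    per_block <- bin_s / block_s
    blk_of <- function(bin) floor((bin - 1L) * per_block) + 1L
    blocks <- lapply(sort(unique(blk_of(bin_tot$bin))), function(b) {
      sel_bins <- bin_tot[blk_of(bin_tot$bin) == b, , drop = FALSE]
      sel_bz <- bz[blk_of(bz$bin) == b, , drop = FALSE]
      dplyr::mutate(agg_zone(sel_bz, sel_bins), block = b, .before = 1)
    })
    out$blocks <- dplyr::bind_rows(blocks)
  }
  out
}

# ---- minimum enclosing ellipse ----------------------------------------------

#' Minimum-area enclosing ellipse of a point set
#'
#' The unique smallest-area closed ellipse containing all points, computed by
#' Khachiyan-type iterative reweighting (Frank-Wolfe with away/drop steps on
#' the lifted D-optimal design problem), run on the convex hull of the input
#' for speed. After convergence the shape matrix is rescaled so containment
#' holds exactly; the area inflation is bounded by the relative tolerance.
#'
#' Degenerate inputs (fewer than 3 distinct points, or all points collinear)
#' return a flagged degenerate fit: the "ellipse" collapses to the segment
#' between the two extreme points, with semi-major axis half the largest
#' pairwise distance and semi-minor axis 0.
#'
#' @param points numeric matrix (n x 2) or data frame with columns x, y.
#' @param tol relative duality-gap tolerance.
#' @param max_iter iteration cap; exceeding it is an error naming the size.
#' @return object of class `ellipse_fit`: `centre`, `a` (semi-major), `b`
#'   (semi-minor), `orientation` (radians, major axis, in (-pi/2, pi/2]),
#'   `degenerate` flag and the shape matrix `A` with
#'   (p - centre)' A (p - centre) <= 1 on all points.
#' @export
min_enclosing_ellipse <- function(points, tol = 1e-7, max_iter = 1e5) {
  P <- as.matrix(points)
  if (is.data.frame(points)) P <- cbind(points$x, points$y)
  if (!nrow(P)) stop("empty point set")
  storage.mode(P) <- "double"
  U <- unique(P)
  # rank of the centred point cloud decides degeneracy
  if (nrow(U) >= 2) {
    ctr <- colMeans(U)
    sv <- svd(sweep(U, 2, ctr))$d
    collinear <- sv[2] <= 1e-9 * max(sv[1], 1e-300)
  } else collinear <- TRUE
  if (nrow(U) < 3 || collinear) {
    if (nrow(U) == 1)
      return(new_ellipse_fit(U[1, ], 0, 0, 0, degenerate = TRUE, A = NULL))
    dirv <- svd(sweep(U, 2, colMeans(U)))$v[, 1]
    proj <- U %*% dirv
    i1 <- which.min(proj); i2 <- which.max(proj)
    a <- (proj[i2] - proj[i1]) / 2
    centre <- (U[i1, ] + U[i2, ]) / 2
    return(new_ellipse_fit(centre, a, 0, atan2(dirv[2], dirv[1]) %% pi,
                           degenerate = TRUE, A = NULL))
  }
  hull <- grDevices::chull(P)
  H <- P[hull, , drop = FALSE]
  fit <- mvee_khachiyan(H, tol = tol, max_iter = max_iter)
  # exact containment over all original points
  d2 <- sweep(P, 2, fit$centre)
  forms <- rowSums((d2 %*% fit$A) * d2)
  fmax <- max(forms)
  if (fmax > 1) fit$A <- fit$A / fmax
  ei <- eigen(fit$A, symmetric = TRUE)
  axes <- 1 / sqrt(ei$values)           # decreasing eigenvalue -> minor first
  major <- ei$vectors[, which.min(ei$values)]
  ang <- atan2(major[2], major[1]) %% pi
  if (ang > pi / 2) ang <- ang - pi
  new_ellipse_fit(fit$centre, max(axes), min(axes), ang,
                  degenerate = FALSE, A = fit$A)
}

new_ellipse_fit <- function(centre, a, b, orientation, degenerate, A) {
  structure(list(centre = as.numeric(centre), a = a, b = b,
                 orientation = orientation, degenerate = degenerate, A = A),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit>%s centre (%.3f, %.3f), a %.4f, b %.4f, theta %.3f rad\n",
              if (x$degenerate) " [degenerate]" else "",
              x$centre[1], x$centre[2], x$a, x$b, x$orientation))
  invisible(x)
}

# Frank-Wolfe with away steps on max log det sum u_i q_i q_i' over the
# simplex, q_i the lifted hull points; linear convergence makes tight
# tolerances affordable.
mvee_khachiyan <- function(H, tol, max_iter) {
  n <- nrow(H); d <- 2
  # centre and scale for conditioning; the fit is affine-equivariant
  mu <- colMeans(H)
  Hc <- sweep(H, 2, mu)
  sc <- max(abs(Hc), 1e-300)
  Hc <- Hc / sc
  q1 <- Hc[, 1]; q2 <- Hc[, 2]   # lifted points (q3 = 1)
  u <- rep(1 / n, n)
  # Stagnation guard: with more than d(d+3)/2 boundary points the optimal
  # design is non-unique and the dual gap floors while the ellipse itself
  # is long converged; stop when log det X gains less than `min_gain` over
  # a `window`-iteration stretch (area suboptimality then ~1e-5 relative).
  window <- 200L
  min_gain <- 1e-7
  ld_buf <- rep(NA_real_, window)
  for (it in seq_len(max_iter)) {
    # X = sum_i u_i q_i q_i' (3x3 symmetric), inverted by adjugate
    uq1 <- u * q1; uq2 <- u * q2
    x11 <- sum(uq1 * q1); x12 <- sum(uq1 * q2); x13 <- sum(uq1)
    x22 <- sum(uq2 * q2); x23 <- sum(uq2); x33 <- 1
    c11 <- x22 * x33 - x23 * x23; c12 <- x13 * x23 - x12 * x33
    c13 <- x12 * x23 - x13 * x22; c22 <- x11 * x33 - x13 * x13
    c23 <- x12 * x13 - x11 * x23; c33 <- x11 * x22 - x12 * x12
    det <- x11 * c11 + x12 * c12 + x13 * c13
    M <- (q1 * (c11 * q1 + c12 * q2 + c13) +
          q2 * (c12 * q1 + c22 * q2 + c23) +
          (c13 * q1 + c23 * q2 + c33)) / det
    jmax <- which.max(M)
    e_plus <- M[jmax] / (d + 1) - 1
    sup <- which(u > 1e-12)
    jmin <- sup[which.min(M[sup])]
    e_minus <- 1 - M[jmin] / (d + 1)
    if (max(e_plus, e_minus) < tol) break
    ld <- log(max(det, 1e-300))
    slot <- it %% window + 1L
    if (!is.na(ld_buf[slot]) && ld - ld_buf[slot] < min_gain) break
    ld_buf[slot] <- ld
    if (it == max_iter)
      stop(sprintf("enclosing ellipse did not converge in %d iterations (n = %d)",
                   max_iter, n))
    if (e_plus >= e_minus) {
      step <- (M[jmax] - d - 1) / ((d + 1) * (M[jmax] - 1))
      u <- u * (1 - step)
      u[jmax] <- u[jmax] + step
    } else {
      step <- (d + 1 - M[jmin]) / ((d + 1) * (M[jmin] - 1))
      cap <- u[jmin] / (1 - u[jmin])
      if (!is.finite(step) || step <= 0 || step > cap) step <- cap
      u <- u * (1 + step)
      u[jmin] <- u[jmin] - step
      u[u < 0] <- 0
      u <- u / sum(u)
    }
  }
  centre <- colSums(u * Hc)
  S <- crossprod(Hc, u * Hc) - tcrossprod(centre)
  list(centre = mu + sc * centre, A = solve(S) / d / sc^2)
}

#' Ellipse quadratic form at points
#'
#' Evaluates (p - centre)' A (p - centre); values <= 1 lie inside or on the
#' ellipse. Errors on degenerate fits, which have no shape matrix.
#'
#' @param fit an [min_enclosing_ellipse()] result.
#' @param points n x 2 matrix.
#' @return numeric vector of quadratic-form values.
#' @export
ellipse_form <- function(fit, points) {
  if (fit$degenerate) stop("degenerate fit has no quadratic form")
  P <- as.matrix(points)
  d2 <- sweep(P, 2, fit$centre)
  rowSums((d2 %*% fit$A) * d2)
}

#' Eccentricity of a fitted ellipse
#'
#' The elongation of the path's minimum enclosing ellipse,
#' `sqrt(1 - (b/a)^2)`: 0 for a circle, 1 in the degenerate (collinear)
#' limit. Used with MPDE as a measure of spatial exploration.
#'
#' @param fit an `ellipse_fit`.
#' @return eccentricity between 0 and 1.
#' @export
eccentricity <- function(fit) {
  if (fit$a == 0) stop("eccentricity undefined: semi-major axis is 0")
  if (fit$degenerate) return(1)
  sqrt(1 - (fit$b / fit$a)^2)
}

#' Mean point distance to the ellipse centre (MPDE)
#'
#' Mean Euclidean distance from each path point to the centre of the path's
#' minimum enclosing ellipse; with eccentricity, a measure of how elongated
#' and spread out the path is.
#'
#' @param points n x 2 matrix or data frame (the segment's points).
#' @param fit the `ellipse_fit` of those points.
#' @return mm.
#' @export
mpde <- function(points, fit) {
  P <- as.matrix(points)
  if (is.data.frame(points)) P <- cbind(points$x, points$y)
  mean(sqrt((P[, 1] - fit$centre[1])^2 + (P[, 2] - fit$centre[2])^2))
}

#' Mean point distance to the well centre (MPDC)
#'
#' Mean Euclidean distance from each path point to the well centre; larger
#' values mean edge preference (thigmotaxis).
#'
#' @param points n x 2 matrix or data frame.
#' @param well a [well_geometry()].
#' @return mm.
#' @export
mpdc <- function(points, well) {
  P <- as.matrix(points)
  if (is.data.frame(points)) P <- cbind(points$x, points$y)
  if (!nrow(P)) stop("empty point set")
  mean(sqrt((P[, 1] - well$centre[1])^2 + (P[, 2] - well$centre[2])^2))
}

# ---- per-larva endpoint extraction ------------------------------------------

#' Full behavioural endpoint vector for one larva
#'
#' Runs the whole chain: zone labels, time budgets and transitions from the
#' unfiltered labels; zone segmentation, the 1st-percentile artefact filter,
#' and per-segment eccentricity / MPDE / MPDC on the kept segments, averaged
#' per zone. Zones the larva never entered get `NA` features (absent, not
#' zero). With `block_s` set, per-block rows are appended after the overall
#' rows.
#'
#' @param traj a [trajectory()].
#' @param well a [well_geometry()].
#' @param thresholds a [speed_thresholds()].
#' @param bin_s budget bin width (s).
#' @param block_s optional block width (s), e.g. 900 for 15-min blocks.
#' @param percentile segment-filter percentile.
#' @param ellipse_tol tolerance for [min_enclosing_ellipse()].
#' @return tibble, one row per zone (x block): identification columns,
#'   `pct_time`, `transitions`, class percentages, `mean_eccentricity`,
#'   `mean_mpde`, `mean_mpdc`, kept/removed segment counts.
#' @export
larva_features <- function(traj, well, thresholds = speed_thresholds(),
                           bin_s = 60, block_s = NULL, percentile = 1,
                           ellipse_tol = 1e-7) {
  labels <- assign_zone(traj, well)
  classes <- classify_speed(instantaneous_speeds(traj), thresholds)
  budgets <- time_budgets(traj, labels, classes, bin_s = bin_s,
                          block_s = block_s)
  segs <- segment_by_zone(traj, labels)
  kept <- filter_short_segments(segs, percentile = percentile)
  removed <- attr(kept, "removed")

  seg_feats <- function(k) {
    pts <- cbind(traj$x[k$start:k$end], traj$y[k$start:k$end])
    fit <- min_enclosing_ellipse(pts, tol = ellipse_tol)
    c(eps = if (fit$a > 0) eccentricity(fit) else NA_real_,
      mpde = mpde(pts, fit), mpdc = mpdc(pts, well))
  }
  sf <- if (nrow(kept)) {
    t(vapply(seq_len(nrow(kept)), function(i) seg_feats(kept[i, ]),
             c(eps = 0, mpde = 0, mpdc = 0)))
  } else matrix(numeric(0), 0, 3,
                dimnames = list(NULL, c("eps", "mpde", "mpdc")))
  blk_of_time <- function(tt) {
    if (is.null(block_s)) rep(NA_integer_, length(tt))
    else floor((tt - traj$t[1]) / block_s) + 1L
  }
  seg_tbl <- tibble::tibble(zone = kept$zone,
                            block = blk_of_time(traj$t[kept$start]),
                            eps = sf[, "eps"], mpde = sf[, "mpde"],
                            mpdc = sf[, "mpdc"])
  geo_means <- function(st, z) {
    rows <- st[st$zone == z & !is.na(st$eps), , drop = FALSE]
    mrows <- st[st$zone == z, , drop = FALSE]
    tibble::tibble(
      mean_eccentricity = if (nrow(rows)) mean(rows$eps) else NA_real_,
      mean_mpde = if (nrow(mrows)) mean(mrows$mpde) else NA_real_,
      mean_mpdc = if (nrow(mrows)) mean(mrows$mpdc) else NA_real_)
  }
  grp <- group_of(traj)
  id_cols <- tibble::tibble(
    larva_id = larva_id_of(traj),
    osmolyte = if (is.null(grp)) NA_character_ else grp$osmolyte,
    snp = if (is.null(grp)) NA else grp$snp)

  one_scope <- function(zrow, st, transitions, block_label) {
    dplyr::bind_cols(
      id_cols, tibble::tibble(block = block_label),
      zrow[, c("zone", "pct_time", "pct_inactive", "pct_low", "pct_high")],
      tibble::tibble(transitions = transitions),
      geo_means(st, zrow$zone),
      tibble::tibble(n_segments_kept = nrow(kept),
                     n_segments_removed = nrow(removed)))
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(budgets$zones)), function(i)
    one_scope(budgets$zones[i, ], seg_tbl, count_transitions(labels),
              "overall")))
  if (!is.null(block_s)) {
    pts_blk <- blk_of_time(traj$t)
    for (b in sort(unique(budgets$blocks$block))) {
      zb <- budgets$blocks[budgets$blocks$block == b, , drop = FALSE]
      stb <- seg_tbl[!is.na(seg_tbl$block) & seg_tbl$block == b, , drop = FALSE]
      trans_b <- count_transitions(labels[pts_blk == b])
      out <- dplyr::bind_rows(out, dplyr::bind_rows(
        lapply(seq_len(nrow(zb)), function(i)
          one_scope(zb[i, ], stb, trans_b, paste0("block", b)))))
    }
  }
  out
}

#' Behavioural endpoints for a cohort of trajectories
#'
#' @param trajs list of [trajectory()] objects.
#' @param well a [well_geometry()].
#' @param ... passed to [larva_features()].
#' @return tibble of stacked per-larva records.
#' @export
cohort_features <- function(trajs, well, ...) {
  dplyr::bind_rows(lapply(trajs, larva_features, well = well, ...))
}
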