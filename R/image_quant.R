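#' Maximum-intensity projection of a stack channel
#'
#' Per-pixel maximum over z; the standard 2-D reduction the vessel and
#' nuclei quantifications start from.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return 2-D matrix `[y, x]`.
#' @export
max_intensity_projection <- function(stack, channel) {
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stop("unknown channel: ", channel)
  out <- ch[, , 1]
  nz <- dim(ch)[3]
  if (nz > 1) for (k in 2:nz) out <- pmax(out, ch[, , k])
  out
}

#' Segment vessels in a 2-D image by intensity thresholding
#'
#' Threshold either derived by Otsu's method or fixed, followed by removal
#' of connected components smaller than `min_object_px`. The realised
#' threshold is logged and attached to the result; the original analysis
#' scripts' constants are unknown, so every run reports its own.
#'
#' @param image 2-D numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold (required for `method = "fixed"`).
#' @param min_object_px minimum component size kept, in pixels.
#' @param smooth_sigma Gaussian pre-smoothing sigma in px (0 disables).
#'   Smoothing regularises the mask boundary so the downstream skeleton
#'   does not wander and over-read vessel length on noisy images.
#' @return logical mask with attribute `threshold`.
#' @export
segment_vessels <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL, min_object_px = 50,
                            smooth_sigma = 1.5) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (smooth_sigma > 0) {
    mx0 <- max(image)
    if (mx0 > 0) image <- EBImage::gblur(image / mx0, sigma = smooth_sigma) * mx0
  }
  mx <- max(image)
  if (mx <= min(image)) stop("no foreground: image is constant")
  thr <- if (method == "otsu") {
    EBImage::otsu(image / mx, range = c(0, 1)) * mx
  } else {
    if (is.null(threshold)) stop("method 'fixed' needs a threshold")
    threshold
  }
  mask <- image > thr
  if (any(mask)) mask <- EBImage::fillHull(mask) > 0
  if (min_object_px > 0 && any(mask)) {
    lbl <- EBImage::bwlabel(mask)
    sizes <- tabulate(lbl)
    mask <- array(lbl %in% which(sizes >= min_object_px), dim(mask))
  }
  if (!any(mask)) stop("no foreground above threshold")
  message(sprintf("segment_vessels: %s threshold %.4g, %d px foreground",
                  method, thr, sum(mask)))
  structure(mask, threshold = thr)
}

# Thinning retracts a skeleton tip by about the local tube radius, while
# the mask's end cap overshoots the true centreline end by the same amount;
# extending each tip halfway to the mask boundary recovers the cap length.
extend_skeleton_tips <- function(sk, mask) {
  nr <- nrow(sk); nc <- ncol(sk)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  pts <- which(sk, arr.ind = TRUE)
  for (i in seq_len(nrow(pts))) {
    r <- pts[i, 1]; c <- pts[i, 2]
    nbr <- NULL
    for (k in seq_len(8)) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && sk[rr, cc])
        nbr <- rbind(nbr, c(rr, cc))
    }
    if (is.null(nbr) || nrow(nbr) != 1) next
    dy <- r - nbr[1, 1]; dx <- c - nbr[1, 2]
    steps <- 0L
    rr <- r; cc <- c
    while (TRUE) {
      rr2 <- rr + dy; cc2 <- cc + dx
      if (rr2 < 1 || rr2 > nr || cc2 < 1 || cc2 > nc || !mask[rr2, cc2]) break
      rr <- rr2; cc <- cc2; steps <- steps + 1L
      if (steps > 200L) break
    }
    ext <- steps %/% 2L
    rr <- r; cc <- c
    for (s in seq_len(ext)) {
      rr <- rr + dy; cc <- cc + dx
      sk[rr, cc] <- TRUE
    }
  }
  sk
}

# One Zhang-Suen sub-iteration on a padded logical matrix.
zs_subiter <- function(m, step) {
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dy, dx) m[(2 + dy):(nr - 1 + dy), (2 + dx):(nc - 1 + dx)]
  p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
  p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
    (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
  cond <- m[2:(nr - 1), 2:(nc - 1)] & b >= 2 & b <= 6 & a == 1
  if (step == 1) {
    cond <- cond & !(p2 & p4 & p6) & !(p4 & p6 & p8)
  } else {
    cond <- cond & !(p2 & p4 & p8) & !(p2 & p6 & p8)
  }
  m[2:(nr - 1), 2:(nc - 1)][cond] <- FALSE
  list(m = m, changed = any(cond))
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iterative thinning to a 1-px-wide 8-connected skeleton, followed by
#' staircase pruning: a pixel with exactly two skeleton neighbours that are
#' themselves mutually adjacent is a redundant corner of a diagonal
#' staircase and is removed (sequentially, so connectivity is preserved).
#' Without the pruning, diagonal runs read ~40% too long.
#'
#' @param mask logical 2-D matrix.
#' @return logical matrix of the same shape.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask != 0
  repeat {
    r1 <- zs_subiter(m, 1)
    r2 <- zs_subiter(r1$m, 2)
    m <- r2$m
    if (!r1$changed && !r2$changed) break
  }
  # staircase pruning
  repeat {
    changed <- FALSE
    for (i in which(m)) {
      nr <- nrow(m)
      rc <- c((i - 1) %% nr + 1, (i - 1) %/% nr + 1)
      nb <- i + c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
      on <- nb[m[nb]]
      if (length(on) == 2) {
        d <- abs(((on[1] - 1) %% nr) - ((on[2] - 1) %% nr))
        dc <- abs(((on[1] - 1) %/% nr) - ((on[2] - 1) %/% nr))
        if (d <= 1 && dc <= 1) {
          m[i] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)]
}

#' Vascular length from a vessel mask
#'
#' Skeletonises the mask and sums centre-to-centre distances over adjacent
#' skeleton-pixel pairs: lateral neighbours contribute one pixel size,
#' diagonal neighbours `sqrt(2)` pixel sizes. Lateral pairs that form a
#' triangle with a diagonally adjacent skeleton pixel are not counted (the
#' diagonal already carries that step); without this triangle reduction a
#' digital staircase reads up to 2/sqrt(2) times too long.
#'
#' @param mask logical 2-D vessel mask.
#' @param pixel_size_um pixel size in um (isotropic in-plane).
#' @return length in um, with the skeleton in attribute `skeleton`.
#' @export
vessel_length <- function(mask, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  if (!any(mask)) stop("empty mask")
  sk <- skeletonize_mask(mask)
  sk <- extend_skeleton_tips(sk, mask != 0)
  p <- matrix(FALSE, nrow(sk) + 2, ncol(sk) + 2)
  p[2:(nrow(sk) + 1), 2:(ncol(sk) + 1)] <- sk
  nr <- nrow(p); nc <- ncol(p)
  sh <- function(dy, dx) p[(2 + dy):(nr - 1 + dy), (2 + dx):(nc - 1 + dx)]
  s00 <- sh(0, 0)
  # horizontal pair (0,0)-(0,1): drop when a pixel above/below either end
  # closes a triangle through a diagonal
  hpair <- s00 & sh(0, 1) &
    !(sh(-1, 0) | sh(-1, 1) | sh(1, 0) | sh(1, 1))
  vpair <- s00 & sh(1, 0) &
    !(sh(0, -1) | sh(1, -1) | sh(0, 1) | sh(1, 1))
  d1 <- s00 & sh(1, 1)    # down-right
  d2 <- s00 & sh(1, -1)   # down-left
  len <- (sum(hpair) + sum(vpair) + sqrt(2) * (sum(d1) + sum(d2))) *
    pixel_size_um
  structure(len, skeleton = sk)
}

#' Channel intensity normalised to vascular length
#'
#' Total signal intensity inside the vessel mask divided by the vascular
#' length: the per-unit-length endothelial expression readout (klf2a:GFP,
#' DAF-FM). Signal outside the mask does not contribute.
#'
#' @param signal_image 2-D matrix (e.g. the green-channel MIP).
#' @param mask logical vessel mask of the same shape.
#' @param length_um vascular length (um), from [vessel_length()].
#' @return intensity per um (a.u./um).
#' @export
normalized_vascular_intensity <- function(signal_image, mask, length_um) {
  stopifnot(all(dim(signal_image) == dim(mask)))
  if (length_um <= 0) stop("vascular length must be positive")
  sum(signal_image[mask != 0]) / length_um
}

check_roi <- function(roi_box, dims) {
  stopifnot(is.list(roi_box), all(c("y", "x", "z") %in% names(roi_box)))
  for (ax in c("y", "x", "z")) {
    r <- roi_box[[ax]]
    if (length(r) != 2 || r[1] < 1 || r[2] > dims[[ax]] || r[1] > r[2])
      stop("ROI out of bounds on axis ", ax)
  }
  invisible(TRUE)
}

#' Mean intensity in a fixed 3-D ROI
#'
#' Mean voxel intensity of one channel over an axis-aligned box, the
#' fixed-tissue-volume readout used for glial and channel markers (GFAP,
#' TRPV4, GS). The ROI is an explicit configuration input; no automatic
#' tectum detection is attempted.
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @param roi_box list with elements `y`, `x`, `z`, each `c(from, to)` in
#'   voxel indices (inclusive).
#' @return mean intensity (a.u.).
#' @export
roi_mean_intensity <- function(stack, channel, roi_box) {
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stop("unknown channel: ", channel)
  d <- dim(ch)
  check_roi(roi_box, list(y = d[1], x = d[2], z = d[3]))
  mean(ch[roi_box$y[1]:roi_box$y[2], roi_box$x[1]:roi_box$x[2],
          roi_box$z[1]:roi_box$z[2]])
}

#' Label connected components in a 3-D binary mask (26-connectivity)
#'
#' Breadth-first labelling on the foreground with all 26 neighbour offsets;
#' the mask is padded so no bounds checks are needed.
#'
#' @param mask logical 3-D array.
#' @return integer array of component labels (0 = background).
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  pd <- d + 2L
  m <- array(FALSE, pd)
  m[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask != 0
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  loffs <- offs[, "dy"] + offs[, "dx"] * pd[1] + offs[, "dz"] * pd[1] * pd[2]
  lab <- array(0L, pd)
  nextlab <- 0L
  for (i in which(m)) {
    if (lab[i] > 0L) next
    nextlab <- nextlab + 1L
    lab[i] <- nextlab
    frontier <- i
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, loffs, `+`)))
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- nextlab
      frontier <- nb
    }
  }
  lab[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

#' Count mural-cell nuclei in a fixed vascular volume
#'
#' Thresholds the (red) nuclear channel inside the ROI, labels 3-D
#' connected components at 26-connectivity, discards components below a
#' minimum physical volume, and counts the rest. With Otsu thresholding the
#' count is invariant to intensity gain.
#'
#' @param stack an [image_stack()].
#' @param channel nuclear channel name.
#' @param roi_box ROI as in [roi_mean_intensity()]; `NULL` for the whole
#'   stack.
#' @param min_blob_um3 minimum component volume kept (um^3).
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold value.
#' @return integer count, with component volumes (um^3) in attribute
#'   `volumes` and the realised threshold in attribute `threshold`.
#' @export
count_mural_nuclei <- function(stack, channel = "red", roi_box = NULL,
                               min_blob_um3 = 4,
                               threshold_method = c("otsu", "fixed"),
                               threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  ch <- stack$channels[[channel]]
  if (is.null(ch)) stop("unknown channel: ", channel)
  d <- dim(ch)
  if (!is.null(roi_box)) {
    check_roi(roi_box, list(y = d[1], x = d[2], z = d[3]))
    ch <- ch[roi_box$y[1]:roi_box$y[2], roi_box$x[1]:roi_box$x[2],
             roi_box$z[1]:roi_box$z[2], drop = FALSE]
  }
  mx <- max(ch)
  if (mx <= min(ch)) stop("no foreground: ROI is constant")
  thr <- if (threshold_method == "otsu") {
    EBImage::otsu(matrix(ch / mx, nrow = dim(ch)[1]), range = c(0, 1)) * mx
  } else {
    if (is.null(threshold)) stop("threshold_method 'fixed' needs a threshold")
    threshold
  }
  lab <- label_components_3d(ch > thr)
  voxel_um3 <- prod(stack$voxel_size)
  vols <- tabulate(lab) * voxel_um3
  keep <- vols >= min_blob_um3
  message(sprintf("count_mural_nuclei: threshold %.4g, %d component(s), %d kept",
                  thr, length(vols), sum(keep)))
  structure(sum(keep), volumes = vols[keep], threshold = thr)
}

#' Vessel-normalised intensity quantification of a two-channel stack
#'
#' The full chain for one larva: maximum-intensity projections, vessel-mask
#' segmentation on the structural channel, skeleton length, and
#' signal-channel intensity per unit vascular length.
#'
#' @param stack an [image_stack()].
#' @param vessel_channel structural channel (vessel label).
#' @param signal_channel expression channel quantified over the mask.
#' @param method,threshold,min_object_px passed to [segment_vessels()].
#' @return list: `mask`, `skeleton`, `threshold`, `length_um`,
#'   `total_intensity`, `normalized_intensity` (a.u./um).
#' @export
quantify_vessels <- function(stack, vessel_channel = "red",
                             signal_channel = "green",
                             method = "otsu", threshold = NULL,
                             min_object_px = 50) {
  mip_v <- max_intensity_projection(stack, vessel_channel)
  mip_s <- max_intensity_projection(stack, signal_channel)
  mask <- segment_vessels(mip_v, method = method, threshold = threshold,
                          min_object_px = min_object_px)
  if (stack$voxel_size[["x"]] != stack$voxel_size[["y"]])
    stop("in-plane voxel size must be isotropic for length extraction")
  len <- vessel_length(mask, stack$voxel_size[["x"]])
  list(mask = mask, skeleton = attr(len, "skeleton"),
       threshold = attr(mask, "threshold"),
       length_um = as.numeric(len),
       total_intensity = sum(mip_s[mask != 0]),
       normalized_intensity = normalized_vascular_intensity(
         mip_s, mask, as.numeric(len)))
}
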