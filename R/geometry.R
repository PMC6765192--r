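#' Well geometry for a half-darkened well
#'
#' Describes one circular well of the tracking plate: its centre and radius in
#' mm, and the light/dark divider, a diameter line through the centre given by
#' a unit normal. The dark half is the side the normal points into, so the
#' signed offset of a point along the normal is positive in the dark half.
#'
#' @param centre numeric length-2, well centre (x, y) in mm. Feature formulas
#'   use well-centred coordinates, so the default is the origin.
#' @param radius well radius in mm (> 0). A 12-well plate well is ~11 mm.
#' @param divider_normal numeric length-2; normalised internally. Points into
#'   the dark half.
#' @return object of class `well_geometry`.
#' @examples
#' well_geometry(radius = 11)
#' @export
well_geometry <- function(centre = c(0, 0), radius = 11,
                          divider_normal = c(1, 0)) {
  stopifnot(length(centre) == 2, is.finite(centre),
            length(radius) == 1, is.finite(radius), radius > 0,
            length(divider_normal) == 2, any(divider_normal != 0))
  n <- divider_normal / sqrt(sum(divider_normal^2))
  structure(list(centre = as.numeric(centre), radius = as.numeric(radius),
                 divider_normal = as.numeric(n)),
            class = "well_geometry")
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf("<well_geometry> centre (%.2f, %.2f) mm, radius %.2f mm, dark-side normal (%.3f, %.3f)\n",
              x$centre[1], x$centre[2], x$radius,
              x$divider_normal[1], x$divider_normal[2]))
  invisible(x)
}

# Signed offset along the divider normal: > 0 means dark half.
divider_offset <- function(well, x, y) {
  (x - well$centre[1]) * well$divider_normal[1] +
    (y - well$centre[2]) * well$divider_normal[2]
}

#' Treatment group of the 2x2 design
#'
#' The study design crosses an osmolyte (20 mM glucose vs the osmotic control
#' mannitol) with co-treatment with the nitric-oxide donor SNP (0.1 mM).
#'
#' @param osmolyte `"mannitol"` or `"glucose"`.
#' @param snp logical, SNP co-treatment.
#' @return object of class `treatment_group`.
#' @export
treatment_group <- function(osmolyte = c("mannitol", "glucose"), snp = FALSE) {
  osmolyte <- match.arg(osmolyte)
  stopifnot(is.logical(snp), length(snp) == 1, !is.na(snp))
  structure(list(osmolyte = osmolyte, snp = snp), class = "treatment_group")
}

#' @export
format.treatment_group <- function(x, ...) {
  paste0(x$osmolyte, if (x$snp) "+SNP" else "")
}

#' @export
print.treatment_group <- function(x, ...) {
  cat("<treatment_group>", format(x), "\n"); invisible(x)
}

#' Convert tracker pixel coordinates to well-centred mm
#'
#' Video trackers export top-left-origin pixel coordinates with y increasing
#' downward; the feature formulas are geometric and unit-bearing, so the
#' package works in well-centred mm with y increasing upward.
#'
#' @param x,y pixel coordinates (top-left origin, y down).
#' @param origin_px pixel coordinates of the well centre.
#' @param mm_per_px scale factor.
#' @return list with components `x`, `y` in mm.
#' @export
px_to_mm <- function(x, y, origin_px, mm_per_px) {
  stopifnot(length(origin_px) == 2, mm_per_px > 0)
  list(x = (x - origin_px[1]) * mm_per_px,
       y = -(y - origin_px[2]) * mm_per_px)
}
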