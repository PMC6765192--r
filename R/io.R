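#' Read a tracked trajectory from a delimited text file
#'
#' Reads tracker exports (time, x, y columns; one larva per file or selected
#' by a larva-id column) and returns a validated [trajectory()] in seconds and
#' well-centred mm. Export dialects are absorbed by a column-name mapping and
#' unit conversions rather than by format-specific parsers.
#'
#' @param path delimited text file with a header.
#' @param well a [well_geometry()].
#' @param col_map named character vector mapping the required fields `t`, `x`,
#'   `y` (and optionally `larva_id`) to column names in the file.
#' @param larva_id larva to select when the file holds several; also used as
#'   the id of the returned trajectory.
#' @param group optional [treatment_group()].
#' @param time_scale multiplier taking the time column to seconds
#'   (e.g. `1e-3` for ms).
#' @param origin coordinate offset subtracted before scaling (e.g. the well
#'   centre in pixels for raw tracker output).
#' @param scale multiplier taking coordinates to mm (e.g. mm-per-pixel).
#' @param flip_y set `TRUE` for image-style coordinates with y increasing
#'   downward.
#' @param tol_mm well-containment slack in mm.
#' @param delim field delimiter.
#' @return a `trajectory` tibble.
#' @export
read_trajectory <- function(path, well,
                            col_map = c(t = "time", x = "x", y = "y"),
                            larva_id = NULL, group = NULL,
                            time_scale = 1, origin = c(0, 0), scale = 1,
                            flip_y = FALSE, tol_mm = 0.5, delim = ",") {
  stopifnot(all(c("t", "x", "y") %in% names(col_map)))
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  missing_cols <- setdiff(unname(col_map[c("t", "x", "y")]), names(df))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if ("larva_id" %in% names(col_map) && col_map[["larva_id"]] %in% names(df)) {
    ids <- df[[col_map[["larva_id"]]]]
    if (!is.null(larva_id)) {
      df <- df[ids == larva_id, , drop = FALSE]
    } else if (length(unique(ids)) > 1L) {
      stop("file holds several larvae; supply larva_id")
    } else larva_id <- unique(ids)
  }
  x <- (df[[col_map[["x"]]]] - origin[1]) * scale
  y <- (df[[col_map[["y"]]]] - origin[2]) * scale
  if (flip_y) y <- -y
  trajectory(t = df[[col_map[["t"]]]] * time_scale, x = x, y = y,
             larva_id = larva_id %||% "larva", group = group,
             well = well, tol_mm = tol_mm)
}

#' Write a trajectory as CSV
#'
#' Columns `time`, `x`, `y` (seconds, mm); the inverse of [read_trajectory()]
#' with default units.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tibble::tibble(time = traj$t, x = traj$x, y = traj$y), path)
  invisible(path)
}

#' Write per-larva feature records as a tidy CSV
#'
#' One row per larva x zone (x 15-min block when present), stable column
#' order, readable back to identical values with [read_features()].
#'
#' @param records a feature tibble from [larva_features()] /
#'   [cohort_features()], or a list of such tibbles.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(records, path) {
  if (is.list(records) && !is.data.frame(records))
    records <- dplyr::bind_rows(records)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("no feature records to write")
  cols <- c("larva_id", "osmolyte", "snp", "block", "zone", "pct_time",
            "transitions", "pct_inactive", "pct_low", "pct_high",
            "mean_eccentricity", "mean_mpde", "mean_mpdc",
            "n_segments_kept", "n_segments_removed")
  readr::write_csv(records[, intersect(cols, names(records))], path)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#' @param path CSV file.
#' @return tibble of per-larva feature records.
#' @export
read_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read / write fluorescence trace tables
#'
#' Plain CSV with columns `t` (s) and `F` (a.u.), one ROI per file or an
#' optional `roi_id` column.
#'
#' @param path CSV file.
#' @param roi_id ROI to select when a `roi_id` column is present.
#' @return tibble with columns `t`, `F`.
#' @export
read_trace <- function(path, roi_id = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("t", "F") %in% names(df))) stop("trace file needs columns t, F")
  if (!is.null(roi_id) && "roi_id" %in% names(df))
    df <- df[df$roi_id == roi_id, , drop = FALSE]
  validate_trace(df$t, df$F)
  tibble::tibble(t = df$t, F = df$F)
}

#' @rdname read_trace
#' @param trace tibble with columns `t`, `F`.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(trace[, c("t", "F")], path)
  invisible(path)
}

validate_trace <- function(t, F) {
  if (length(t) < 10) stop("trace too short (< 10 samples)")
  dt <- diff(t)
  if (any(dt <= 0)) stop("trace time not strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt) + 1e-12)
    stop("trace sampling is not uniform")
  if (any(F < 0)) stop("fluorescence must be non-negative")
  invisible(TRUE)
}

# ---- image stacks -----------------------------------------------------------

#' Multi-channel 3-D image stack
#'
#' Channels are named 3-D arrays indexed `[y, x, z]` sharing one shape;
#' `voxel_size` is the physical voxel size in micrometres per axis
#' (x, y, z). The imaging default is 0.6 x 0.6 um in-plane with 1 um slices.
#'
#' @param channels named list of 3-D arrays `[y, x, z]`.
#' @param voxel_size numeric length-3, um per axis, named x/y/z.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size = c(x = 0.6, y = 0.6, z = 1.0)) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) stop("channels must be 3-D arrays")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("channels must share one shape")
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  names(voxel_size) <- c("x", "y", "z")
  structure(list(channels = channels, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d channel(s) [%s], %d x %d x %d (y,x,z), voxel %.2f x %.2f x %.2f um\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3],
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"]))
  invisible(x)
}

#' Write an image stack as multi-page TIFF
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...)
#' as 16-bit grayscale; intensities are stored as `value / 65535`. A JSON
#' sidecar `<path>.json` records channel names, slice count, voxel size and
#' the intensity scale so [read_stack()] can reconstruct the stack without
#' extra arguments.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(vapply(stack$channels, max, 0))
  if (mx > 65535) stop("intensities exceed 16-bit range")
  pages <- list()
  for (ch in stack$channels)
    for (k in seq_len(dim(ch)[3]))
      pages[[length(pages) + 1L]] <- ch[, , k] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(channels = names(stack$channels),
         n_z = dim(stack$channels[[1]])[3],
         voxel_size_um = as.list(stack$voxel_size),
         intensity_scale = 65535),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Layout and voxel size come from the JSON sidecar written by
#' [write_stack()] when present, otherwise from the arguments. With neither
#' a sidecar nor an explicit `voxel_size`, reading fails: physical units are
#' required for every downstream quantification.
#'
#' @param path TIFF file (pages channel-major in z).
#' @param channel_names channel names, used when no sidecar exists; the page
#'   count must be divisible by the number of channels.
#' @param voxel_size um per axis (x, y, z), used when no sidecar exists.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, channel_names = NULL, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!length(pages)) stop("no pages in ", path)
  sidecar <- paste0(path, ".json")
  scale <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    channel_names <- meta$channels
    voxel_size <- unlist(meta$voxel_size_um)
    scale <- meta$intensity_scale %||% 1
  }
  if (is.null(voxel_size))
    stop("voxel size unknown: no sidecar and no voxel_size argument")
  channel_names <- channel_names %||% "ch1"
  nc <- length(channel_names)
  if (length(pages) %% nc != 0)
    stop("page count not divisible by number of channels")
  nz <- length(pages) %/% nc
  chans <- setNames(vector("list", nc), channel_names)
  for (i in seq_len(nc)) {
    arr <- array(0, c(dim(pages[[1]]), nz))
    for (k in seq_len(nz)) arr[, , k] <- pages[[(i - 1L) * nz + k]] * scale
    chans[[i]] <- round(arr)
  }
  image_stack(chans, voxel_size = voxel_size)
}

#' Read an analysis configuration file
#'
#' YAML with well geometry, frame rate, speed thresholds, column mappings and
#' image-quantification settings; values are returned as a plain named list
#' with a `well_geometry` built when `well:` is present.
#'
#' @param path YAML file.
#' @return named list; element `well` is a [well_geometry()] when configured.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$well)) {
    w <- cfg$well
    cfg$well <- well_geometry(
      centre = unlist(w$centre %||% c(0, 0)),
      radius = w$radius %||% 11,
      divider_normal = unlist(w$divider_normal %||% c(1, 0)))
  }
  cfg
}
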