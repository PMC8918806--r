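# Volume, mask, landmark, ROI and transform I/O, plus the shared geometric
# primitives (cropping, lateral downsampling, projections).
#
# Canonical on-disk formats: multi-page 8/16-bit TIFF for volumes and masks
# (the acquisition pipeline converts native microscope files to TIFF before
# analysis), CSV with header `name,x_um,y_um,z_um` for landmarks, JSON for
# ROIs and transforms. Spacing is never guessed from a file: it must be
# given explicitly.

#' Read a 3D volume from a multi-page TIFF
#'
#' @param path path to a multi-page 8- or 16-bit TIFF stack.
#' @param spacing voxel size in micrometres, `(x, y, z)` order; required
#'   (TIFF carries no trusted spacing metadata here).
#' @return a [voxel_grid] with integer-valued intensities on the native
#'   bit-depth scale.
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, spacing = NULL) {
  if (is.null(spacing))
    stop("missing required field `spacing` (x, y, z in micrometres)")
  slices <- read_tiff_slices(path)
  if (length(slices) < 2L)
    stop("not a 3D stack: file has a single page")
  arr <- slices_to_array(slices)
  bits <- attr(slices, "bits")
  voxel_grid(arr, spacing, dtype_range = c(0, 2^bits - 1))
}

#' Write a [voxel_grid] as a multi-page TIFF
#'
#' Intensities are stored on the grid's `dtype_range` scale; `bits` selects
#' 8- or 16-bit output. Round-trips through [read_volume()] are bit-exact
#' for integer-valued data within range.
#'
#' @param grid a [voxel_grid].
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @export
write_volume <- function(grid, path, bits = 16L) {
  stopifnot(is_voxel_grid(grid))
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16")
  mx <- 2^bits - 1
  v <- grid$data
  if (min(v) < 0 || max(v) > mx)
    stop(sprintf("data outside the %d-bit range [0, %d]", bits, mx))
  pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , , drop = TRUE] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Read / write a binary vessel mask
#'
#' Masks are stored as 8-bit TIFF with foreground 255 and background 0 (any
#' non-zero pixel reads back as foreground). `inverted = TRUE` uses the
#' opposite convention (vessel = 0, background = 255) for compatibility
#' with histogram-based tools that count vessels as black voxels.
#'
#' @param path TIFF path.
#' @param spacing voxel size `(x, y, z)` in micrometres.
#' @param inverted logical; use the vessel-equals-zero convention.
#' @return [read_mask()] returns a [binary_mask].
#' @export
read_mask <- function(path, spacing = NULL, inverted = FALSE) {
  if (is.null(spacing))
    stop("missing required field `spacing` (x, y, z in micrometres)")
  slices <- read_tiff_slices(path)
  if (length(slices) < 2L)
    stop("not a 3D stack: file has a single page")
  arr <- slices_to_array(slices)
  m <- (arr > 0) * 1L
  if (inverted) m <- 1L - m
  dim(m) <- dim(arr)
  binary_mask(m, spacing)
}

#' @rdname read_mask
#' @param mask a [binary_mask] to write.
#' @export
write_mask <- function(mask, path, inverted = FALSE) {
  stopifnot(is_binary_mask(mask))
  v <- mask$data
  if (inverted) v <- 1L - v
  pages <- lapply(seq_len(dim(v)[1]), function(k) v[k, , , drop = TRUE] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

read_tiff_slices <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  if (any(!vapply(slices, is.matrix, logical(1))))
    stop("unsupported TIFF content: expected single-channel greyscale pages")
  bits <- if (max(vapply(slices, max, numeric(1))) > 255) 16L else 8L
  attr(slices, "bits") <- bits
  slices
}

slices_to_array <- function(slices) {
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]])
  nz <- length(slices)
  arr <- array(0, c(nz, ny, nx))
  for (k in seq_len(nz)) arr[k, , ] <- slices[[k]]
  arr
}

#' Landmark CSV I/O
#'
#' CSV with header `name,x_um,y_um,z_um`, coordinates in physical
#' micrometres.
#'
#' @param path CSV path.
#' @return a [landmark_set].
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x_um", "y_um", "z_um")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns name,x_um,y_um,z_um")
  landmark_set(df$name, df$x_um, df$y_um, df$z_um)
}

#' @rdname read_landmarks
#' @param lm a [landmark_set] to write.
#' @export
write_landmarks <- function(lm, path) {
  write.csv(as.data.frame(lm), path, row.names = FALSE)
  invisible(path)
}

#' ROI JSON I/O (`{"lo":[z,y,x],"hi":[z,y,x]}`, 0-based half-open)
#' @param path JSON path.
#' @return a [roi_box].
#' @export
read_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$lo) || is.null(j$hi)) stop("ROI JSON must have `lo` and `hi`")
  roi_box(j$lo, j$hi)
}

#' @rdname read_roi
#' @param roi a [roi_box] to write.
#' @export
write_roi <- function(roi, path) {
  jsonlite::write_json(list(lo = roi$lo, hi = roi$hi), path,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Crop a volume or mask to a region of interest
#'
#' @param x a [voxel_grid] or [binary_mask].
#' @param roi a [roi_box] within bounds (0-based, half-open, `(z, y, x)`).
#' @return object of the same class restricted to the ROI; shape is
#'   `hi - lo` per axis.
#' @export
crop_to_roi <- function(x, roi) {
  stopifnot(is_voxel_grid(x) || is_binary_mask(x))
  check_roi_bounds(roi, x)
  sub <- x$data[(roi$lo[1] + 1L):roi$hi[1],
                (roi$lo[2] + 1L):roi$hi[2],
                (roi$lo[3] + 1L):roi$hi[3], drop = FALSE]
  if (is_binary_mask(x)) binary_mask(sub, x$spacing)
  else voxel_grid(sub, x$spacing, dtype_range = x$dtype_range)
}

# bilinear resize of one (ny, nx) slice to (my, mx), pixel-centre aligned
resize_slice_bilinear <- function(s, my, mx) {
  ny <- nrow(s); nx <- ncol(s)
  map_axis <- function(m, n) {
    # output pixel centre i (0-based) -> input coordinate
    cc <- (seq_len(m) - 0.5) * (n / m) - 0.5
    c0 <- floor(cc)
    f <- cc - c0
    i0 <- pmin(pmax(c0, 0), n - 1) + 1L
    i1 <- pmin(pmax(c0 + 1, 0), n - 1) + 1L
    list(i0 = as.integer(i0), i1 = as.integer(i1), f = f)
  }
  ay <- map_axis(my, ny); ax <- map_axis(mx, nx)
  wy <- ay$f; wx <- ax$f
  s00 <- s[ay$i0, ax$i0, drop = FALSE]; s01 <- s[ay$i0, ax$i1, drop = FALSE]
  s10 <- s[ay$i1, ax$i0, drop = FALSE]; s11 <- s[ay$i1, ax$i1, drop = FALSE]
  wy1 <- 1 - wy; wx1 <- 1 - wx
  s00 * (wy1 %o% wx1) + s01 * (wy1 %o% wx) +
    s10 * (wy %o% wx1) + s11 * (wy %o% wx)
}

#' Downsample the lateral (x, y) axes by bilinear interpolation
#'
#' Resamples each z-slice to `target_xy` pixels laterally (the workflow
#' downsamples 1920 to 512 before the distance-map and skeleton stages to
#' reduce processing cost); the z axis is untouched and the lateral spacing
#' is rescaled by the size ratio. Binary masks are interpolated and
#' re-thresholded at 0.5.
#'
#' @param grid a [voxel_grid] or [binary_mask].
#' @param target_xy target lateral size in pixels (applied to both x and y,
#'   preserving the aspect ratio via per-axis ratios when `ny != nx`).
#' @return same class as `grid`, lateral size `target_xy`.
#' @export
downsample_xy <- function(grid, target_xy) {
  stopifnot(is_voxel_grid(grid) || is_binary_mask(grid))
  target_xy <- as.integer(target_xy)
  if (target_xy <= 0L) stop("`target_xy` must be positive")
  d <- dim(grid$data)
  if (target_xy > d[2] || target_xy > d[3])
    stop("`target_xy` exceeds current lateral size")
  my <- target_xy; mx <- target_xy
  out <- array(0, c(d[1], my, mx))
  for (k in seq_len(d[1]))
    out[k, , ] <- resize_slice_bilinear(grid$data[k, , , drop = TRUE], my, mx)
  sp <- grid$spacing
  sp["y"] <- sp["y"] * d[2] / my
  sp["x"] <- sp["x"] * d[3] / mx
  if (is_binary_mask(grid)) binary_mask((out > 0.5) * 1L, sp)
  else voxel_grid(out, sp, dtype_range = grid$dtype_range)
}

#' Maximum intensity projection
#'
#' @param x a [voxel_grid] or [binary_mask].
#' @param axis axis to project over: `"z"` (default, gives a `(y, x)`
#'   image), `"y"` or `"x"`.
#' @return a 2D matrix of per-column maxima.
#' @export
max_intensity_projection <- function(x, axis = c("z", "y", "x")) {
  stopifnot(is_voxel_grid(x) || is_binary_mask(x))
  axis <- match.arg(axis)
  keep <- switch(axis, z = c(2, 3), y = c(1, 3), x = c(1, 2))
  apply(x$data, keep, max)
}
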