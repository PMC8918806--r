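# Domain containers. Arrays are indexed (z, y, x): dim(data) = c(nz, ny, nx).
# Physical coordinates are (x, y, z) in micrometres with the coordinate of
# voxel centre (iz, iy, ix) (0-based) equal to (ix*sx, iy*sy, iz*sz).

#' 3D scalar volume with physical voxel spacing
#'
#' A `voxel_grid` wraps a numeric 3D array indexed `(z, y, x)` together with
#' the physical voxel size in micrometres. It is the container for raw,
#' enhanced and distance-map volumes throughout the package.
#'
#' @param data numeric 3D array, indexed `(z, y, x)`.
#' @param spacing numeric length-3 voxel size in micrometres, in `(x, y, z)`
#'   order (lateral x, lateral y, axial z). All entries must be positive.
#' @param dtype_range optional length-2 numeric giving the intensity dynamic
#'   range (e.g. `c(0, 65535)` for 16-bit data); used by SSIM and Otsu
#'   binning. Defaults to the data range.
#' @return an object of class `voxel_grid` with fields `data`, `spacing`
#'   (named `x`, `y`, `z`) and `dtype_range`.
#' @examples
#' g <- voxel_grid(array(0, c(4, 8, 8)), spacing = c(0.33, 0.33, 0.5))
#' dim(g$data)
#' @export
voxel_grid <- function(data, spacing, dtype_range = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  if (any(dim(data) < 1L)) stop("`data` must have at least 1 voxel per axis")
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("intensities must be finite")
  spacing <- check_spacing(spacing)
  if (is.null(dtype_range)) dtype_range <- range(data)
  structure(list(data = data, spacing = spacing,
                 dtype_range = as.numeric(dtype_range)),
            class = "voxel_grid")
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive values (x, y, z) in micrometres")
  names(spacing) <- c("x", "y", "z")
  spacing
}

#' Binary 3D mask (vessel foreground = 1)
#'
#' Container for binary volumes: segmentations, registered masks and
#' skeletons. Foreground (vessel) voxels are 1, background 0; use the
#' `inverted` flag of [write_mask()]/[read_mask()] for tools using the
#' opposite convention.
#'
#' @param data 3D array coercible to 0/1, indexed `(z, y, x)`.
#' @param spacing as in [voxel_grid()].
#' @return an object of class `binary_mask` with integer 0/1 `data`.
#' @export
binary_mask <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed (z, y, x)")
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  } else {
    storage.mode(data) <- "integer"
    if (!all(data %in% c(0L, 1L)))
      stop("mask values must be 0/1")
  }
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = "binary_mask")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g um (x,y,z), range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$spacing["x"], x$spacing["y"], x$spacing["z"],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g um (x,y,z), %d foreground voxels\n",
              d[1], d[2], d[3], x$spacing["x"], x$spacing["y"], x$spacing["z"],
              sum(x$data)))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")
is_binary_mask <- function(x) inherits(x, "binary_mask")

# voxel volume in um^3
voxel_volume <- function(x) prod(x$spacing)

#' Rectangular region of interest in voxel indices
#'
#' Bounds are 0-based and half-open (`lo` inclusive, `hi` exclusive), in
#' `(z, y, x)` index order, matching the on-disk JSON representation
#' `{"lo":[z,y,x],"hi":[z,y,x]}`.
#'
#' @param lo,hi integer length-3 bounds `(z, y, x)`; `lo < hi` per axis.
#' @return an object of class `roi_box`.
#' @examples
#' roi_box(c(0, 0, 0), c(10, 64, 64))
#' @export
roi_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L)
    stop("`lo` and `hi` must each have three entries (z, y, x)")
  if (any(lo < 0L)) stop("`lo` must be non-negative")
  if (any(lo >= hi)) stop("`lo` must be strictly below `hi` on every axis")
  structure(list(lo = lo, hi = hi), class = "roi_box")
}

full_roi <- function(x) {
  d <- dim(x$data)
  roi_box(c(0L, 0L, 0L), d)
}

check_roi_bounds <- function(roi, x) {
  d <- dim(x$data)
  if (any(roi$hi > d))
    stop("ROI exceeds grid bounds")
  invisible(roi)
}

#' Named anatomical landmark set
#'
#' Ordered named 3D points in physical micrometres, used for manual rigid
#' registration (the workflow uses 11 anatomical landmarks per sample) and
#' for midline axis specification.
#'
#' @param name character vector of landmark names.
#' @param x,y,z numeric coordinates in micrometres.
#' @return a `landmark_set`: a data.frame with columns
#'   `name, x_um, y_um, z_um`.
#' @export
landmark_set <- function(name, x, y, z) {
  if (anyDuplicated(name)) stop("landmark names must be unique")
  n <- length(name)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("coordinate vectors must match `name` in length")
  structure(data.frame(name = as.character(name), x_um = as.numeric(x),
                       y_um = as.numeric(y), z_um = as.numeric(z),
                       stringsAsFactors = FALSE),
            class = c("landmark_set", "data.frame"))
}

landmark_matrix <- function(lm) {
  as.matrix(lm[, c("x_um", "y_um", "z_um")])
}
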