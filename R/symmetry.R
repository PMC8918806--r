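# Intra-sample left-right symmetry: anterior-posterior axis alignment,
# midline mirroring, voxel-overlap similarity and per-hemisphere metrics.

#' Midline axis from anatomical anchor points
#'
#' The anterior-posterior midline is specified by named points placed
#' along the midline vessels (in the real workflow: along the basilar
#' artery, between the left-right posterior communicating segments and
#' metencephalic arteries, and at the anterior cerebral vein bifurcation);
#' a straight line is fitted through them.
#'
#' @param points a [landmark_set] with at least 2 distinct points
#'   (micrometres).
#' @return a `midline_axis` with the points and the unit direction of the
#'   fitted line (first principal direction).
#' @export
midline_axis <- function(points) {
  P <- landmark_matrix(points)
  if (nrow(P) < 2L) stop("midline axis needs at least 2 points")
  Pc <- sweep(P, 2, colMeans(P))
  if (max(abs(Pc)) < 1e-12) stop("coincident axis points")
  dir <- svd(Pc)$v[, 1]
  if (dir[2] < 0) dir <- -dir  # orient towards +y (posterior)
  structure(list(points = points, direction = dir / sqrt(sum(dir^2))),
            class = "midline_axis")
}

#' Align the anterior-posterior axis with the image y-axis
#'
#' Rotates the mask in-plane (about the image z-axis, around the volume
#' centre) so that the fitted midline direction becomes parallel to the
#' image y-axis, the orientation required before left-right mirroring.
#'
#' @param mask a [binary_mask].
#' @param axis a [midline_axis] (or [landmark_set], converted).
#' @return list with `mask` (rotated, nearest-neighbour), `transform`
#'   (the [rigid_transform] applied), `angle_deg` (rotation about z) and
#'   `axis` (the transformed axis points).
#' @export
align_ap_axis <- function(mask, axis) {
  stopifnot(is_binary_mask(mask))
  if (inherits(axis, "landmark_set")) axis <- midline_axis(axis)
  dir <- axis$direction
  if (sqrt(dir[1]^2 + dir[2]^2) < 1e-9)
    stop("axis direction is parallel to z: in-plane angle undefined")
  # angle of the (x, y) projection measured from +y towards +x; rotating
  # by that angle about z (Rz(a): x' = x cos a - y sin a) maps the axis
  # direction (sin a, cos a) onto +y
  ang <- atan2(dir[1], dir[2]) * 180 / pi
  d <- dim(mask$data)
  sp <- mask$spacing
  center <- c((d[3] - 1) / 2 * sp[["x"]], (d[2] - 1) / 2 * sp[["y"]],
              (d[1] - 1) / 2 * sp[["z"]])
  xf <- rigid_transform(euler_to_rotmat(ang, 0, 0), c(0, 0, 0), center)
  list(mask = apply_rigid(mask, xf, "nearest"),
       transform = xf, angle_deg = ang,
       axis = midline_axis(transform_landmarks(axis$points, xf)))
}

#' Split at the midline and mirror right onto left
#'
#' The volume is split at the voxel column `midline_x`; the right
#' hemisphere (`x > midline_x`) is reflected across the midline plane
#' (`x -> 2 * midline_x - x`, voxel-centre convention) into the left
#' hemisphere's frame. Both returned masks have the full input shape, with
#' zeros outside their hemisphere, so they can be compared voxel-by-voxel.
#' The midline column itself maps onto itself and belongs to neither
#' hemisphere.
#'
#' @param mask a [binary_mask].
#' @param midline_x 0-based midline voxel column.
#' @return list with `left`, `mirrored_right` (both [binary_mask]s),
#'   `right` (unreflected right hemisphere) and `flagged` (TRUE when the
#'   midline sits at the image edge, leaving one hemisphere empty).
#' @export
mirror_right_to_left <- function(mask, midline_x) {
  stopifnot(is_binary_mask(mask))
  d <- dim(mask$data)
  m <- as.integer(round(midline_x))
  if (m < 0L || m > d[3] - 1L) stop("midline outside the x-range")
  flagged <- m == 0L || m == d[3] - 1L
  left <- mask$data
  if (m + 1L <= d[3]) left[, , (m + 1L):d[3]] <- 0L
  left[, , min(m + 1L, d[3])] <- 0L  # exclude the midline column
  left_arr <- mask$data
  left_arr[, , ] <- 0L
  if (m >= 1L) left_arr[, , 1:m] <- mask$data[, , 1:m, drop = FALSE]
  right_arr <- mask$data
  right_arr[, , ] <- 0L
  if (m + 2L <= d[3])
    right_arr[, , (m + 2L):d[3]] <- mask$data[, , (m + 2L):d[3], drop = FALSE]
  mir <- right_arr
  mir[, , ] <- 0L
  # reflect: source column x (0-based, > m) -> 2m - x when inside the image
  xs <- (m + 1L):(d[3] - 1L)
  xs <- xs[xs <= d[3] - 1L & (2L * m - xs) >= 0L]
  if (m + 2L <= d[3] && length(xs) > 0L)
    mir[, , 2L * m - xs + 1L] <- mask$data[, , xs + 1L, drop = FALSE]
  if (flagged)
    warning("midline at the image edge: one hemisphere is empty")
  list(left = binary_mask(left_arr, mask$spacing),
       mirrored_right = binary_mask(mir, mask$spacing),
       right = binary_mask(right_arr, mask$spacing),
       flagged = flagged)
}

#' Left-right symmetry report
#'
#' Optionally aligns the anterior-posterior axis with the image y-axis,
#' splits at the midline, mirrors the right hemisphere onto the left, and
#' reports per-hemisphere vascular volume and skeleton network length,
#' the left/mirrored-right Dice coefficient, and the overlap mask (voxels
#' that are vessel in both the left and the mirrored right vasculature).
#'
#' @param mask segmented [binary_mask].
#' @param axis optional [midline_axis] or [landmark_set]; when given, the
#'   mask is axis-aligned first and the default midline column is the mean
#'   x of the aligned axis points (rounded half up).
#' @param midline_x 0-based midline voxel column; required when `axis` is
#'   `NULL`.
#' @return a `symmetry_report`: list with `volume_left`, `volume_right`
#'   (um^3), `length_left`, `length_right` (skeleton voxels), `dice_lr`,
#'   `overlap_mask`, `midline_x`, and `flagged` (empty input or edge
#'   midline).
#' @export
left_right_report <- function(mask, axis = NULL, midline_x = NULL) {
  stopifnot(is_binary_mask(mask))
  transform <- NULL
  if (!is.null(axis)) {
    al <- align_ap_axis(mask, axis)
    mask <- al$mask
    transform <- al$transform
    if (is.null(midline_x)) {
      sp <- mask$spacing
      mx_um <- mean(landmark_matrix(al$axis$points)[, 1])
      midline_x <- floor(mx_um / sp[["x"]] + 0.5)  # round half up
    }
  }
  if (is.null(midline_x))
    stop("`midline_x` is required when no axis is given")
  empty <- sum(mask$data) == 0L
  sp <- mirror_right_to_left(mask, midline_x)
  vol_l <- vascular_volume(sp$left)
  vol_r <- vascular_volume(sp$right)
  skel_len <- function(m) {
    if (sum(m$data) == 0L) return(0L)
    network_length(skeletonize_3d(m))$length_voxels
  }
  len_l <- skel_len(sp$left)
  len_r <- skel_len(sp$right)
  ov <- binary_overlap_metrics(sp$left, sp$mirrored_right)
  overlap <- binary_mask((sp$left$data & sp$mirrored_right$data) * 1L,
                         mask$spacing)
  structure(list(volume_left = vol_l, volume_right = vol_r,
                 length_left = len_l, length_right = len_r,
                 dice_lr = ov$dice, overlap_mask = overlap,
                 midline_x = midline_x, transform = transform,
                 flagged = empty || sp$flagged || ov$degenerate),
            class = "symmetry_report")
}

#' @export
print.symmetry_report <- function(x, ...) {
  cat(sprintf("<symmetry_report> V_left %.4g um^3, V_right %.4g um^3, L_left %d, L_right %d, Dice(L, mirrored R) %.4f%s\n",
              x$volume_left, x$volume_right, x$length_left, x$length_right,
              x$dice_lr, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}
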