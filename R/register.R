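# Rigid inter-sample registration: landmark-based least-squares fitting,
# automatic intensity/mask-based registration with a coarse exhaustive
# orientation search followed by multi-resolution local refinement, rigid
# resampling, and population average maps.

#' Rigid transform acting on physical coordinates
#'
#' Maps a physical point `p` (micrometres, `(x, y, z)`) to
#' `R %*% (p - center) + center + t`.
#'
#' @param R 3x3 rotation matrix (orthonormal, determinant +1).
#' @param t translation vector, micrometres.
#' @param center rotation centre, micrometres.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3))) stop("R must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    stop("R is not orthonormal (R'R != I)")
  if (abs(det(R) - 1) > 1e-9)
    stop("R must be a proper rotation (det R = +1)")
  structure(list(R = R, t = as.numeric(t), center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotmat_to_euler(x$R)
  cat(sprintf("<rigid_transform> euler zyx (%.3f, %.3f, %.3f) deg, t = (%.3f, %.3f, %.3f) um, center = (%.3f, %.3f, %.3f) um\n",
              ang[1], ang[2], ang[3], x$t[1], x$t[2], x$t[3],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

# z-y-x Euler angles in degrees -> rotation matrix
euler_to_rotmat <- function(rz, ry, rx) {
  a <- rz * pi / 180; b <- ry * pi / 180; c <- rx * pi / 180
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

rotmat_to_euler <- function(R) {
  ry <- asin(-R[3, 1])
  if (abs(cos(ry)) > 1e-12) {
    rz <- atan2(R[2, 1], R[1, 1])
    rx <- atan2(R[3, 2], R[3, 3])
  } else {  # gimbal lock
    rz <- atan2(-R[1, 2], R[2, 2])
    rx <- 0
  }
  c(rz, ry, rx) * 180 / pi
}

#' Transform JSON I/O (4x4 homogeneous matrix, row-major, physical um)
#' @param xf a [rigid_transform].
#' @param path JSON path.
#' @export
write_transform <- function(xf, path) {
  A <- diag(4)
  A[1:3, 1:3] <- xf$R
  A[1:3, 4] <- xf$t + xf$center - xf$R %*% xf$center
  jsonlite::write_json(list(matrix = as.vector(t(A)),
                            center = xf$center),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- matrix(j$matrix, 4, 4, byrow = TRUE)
  rigid_transform(R = A[1:3, 1:3], t = A[1:3, 4], center = c(0, 0, 0))
}

#' Least-squares rigid fit between two landmark sets
#'
#' Finds the rotation and translation (no scaling) minimising
#' \eqn{\sum_i \| R (p_i - c) + c + t - q_i \|^2} over corresponding
#' landmarks (Kabsch/Procrustes solution via SVD of the cross-covariance;
#' the rotation centre `c` is the moving centroid).
#'
#' @param moving,target [landmark_set]s with identical names in the same
#'   order; at least 3 non-collinear points.
#' @return list with `transform` (a [rigid_transform]) and `rms_residual`
#'   (micrometres).
#' @export
fit_landmark_rigid <- function(moving, target) {
  if (nrow(moving) != nrow(target) ||
      !identical(moving$name, target$name))
    stop("landmark sets must share names and order")
  if (nrow(moving) < 3L) stop("at least 3 landmarks are required")
  P <- landmark_matrix(moving)
  Q <- landmark_matrix(target)
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  sv <- svd(crossprod(Pc, Qc))        # H = Pc' Qc
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("collinear landmark configuration: rotation is not identifiable")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  xf <- rigid_transform(R = R, t = qc - pc, center = pc)
  fitted <- t(R %*% t(sweep(P, 2, pc))) + matrix(qc, nrow(P), 3, byrow = TRUE)
  rms <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(transform = xf, rms_residual = rms)
}

#' Apply a rigid transform to landmark points
#' @param lm a [landmark_set].
#' @param xf a [rigid_transform].
#' @return transformed [landmark_set].
#' @export
transform_landmarks <- function(lm, xf) {
  P <- landmark_matrix(lm)
  Pc <- sweep(P, 2, xf$center)
  Q <- t(xf$R %*% t(Pc)) +
    matrix(xf$center + xf$t, nrow(P), 3, byrow = TRUE)
  landmark_set(lm$name, Q[, 1], Q[, 2], Q[, 3])
}

#' Resample a volume or mask through a rigid transform
#'
#' The transform maps moving physical coordinates into the target frame;
#' the output is sampled on the target geometry (by default the input's
#' own geometry) through the inverse mapping. Masks always use
#' nearest-neighbour interpolation and stay strictly 0/1.
#'
#' @param x a [voxel_grid] or [binary_mask].
#' @param xf a [rigid_transform].
#' @param interpolation `"linear"` or `"nearest"` (grids only; masks are
#'   forced to nearest).
#' @param target optional [voxel_grid]/[binary_mask] supplying the output
#'   geometry.
#' @return transformed object of the same class as `x`.
#' @export
apply_rigid <- function(x, xf, interpolation = c("linear", "nearest"),
                        target = NULL) {
  stopifnot(is_voxel_grid(x) || is_binary_mask(x))
  interpolation <- match.arg(interpolation)
  if (is_binary_mask(x)) interpolation <- "nearest"
  out_like <- if (is.null(target)) x else target
  out_dim <- dim(out_like$data)
  sp_in <- x$spacing; sp_out <- out_like$spacing
  # inverse map: input physical q = R'(p - c - t) + c for output physical p
  Rinv <- t(xf$R)
  # index maps (x, y, z): idx_in = Din^-1 (Rinv Sout idx_out + Rinv(-c-t)+c)
  M <- diag(1 / sp_in) %*% Rinv %*% diag(sp_out)
  b <- as.vector(diag(1 / sp_in) %*% (Rinv %*% (-xf$center - xf$t) + xf$center))
  perm <- c(3, 2, 1)  # reorder (x,y,z) -> (z,y,x) for array indexing
  A_zyx <- M[perm, perm]; b_zyx <- b[perm]
  arr <- resample_affine_cpp(x$data * 1.0, as.integer(out_dim),
                             as.numeric(A_zyx), as.numeric(b_zyx),
                             interpolation == "linear", 0.0)
  if (is_binary_mask(x)) {
    m <- (arr > 0.5) * 1L
    dim(m) <- out_dim
    binary_mask(m, sp_out)
  } else {
    voxel_grid(arr, sp_out, dtype_range = x$dtype_range)
  }
}

#' Compose two rigid transforms (`second` after `first`)
#' @param first,second [rigid_transform]s.
#' @return the composite [rigid_transform] (centre 0).
#' @export
compose_rigid <- function(second, first) {
  # p -> R2 (R1 (p - c1) + c1 + t1 - c2) + c2 + t2
  R <- second$R %*% first$R
  off1 <- first$center + first$t - first$R %*% first$center
  t <- as.vector(second$R %*% (off1 - second$center) + second$center +
                   second$t)
  rigid_transform(R = R, t = t, center = c(0, 0, 0))
}

#' Automatic-registration parameters
#'
#' Settings for [register_automatic_rigid()]: exhaustive coarse orientation
#' search at the coarsest pyramid level, keeping the best few orientations
#' for derivative-free refinement through the downsampling pyramid (the
#' protocol this follows uses five best matching orientations, two- to
#' six-fold downsampling and a squared-difference objective).
#'
#' @param n_orientations_kept candidate orientations refined (default 5).
#' @param downsample_factors descending integer pyramid factors.
#' @param angular_grid_step coarse Euler-angle grid step, degrees.
#' @param angular_range half-range of the coarse search per Euler angle,
#'   degrees (180 searches all orientations).
#' @param max_shift largest admissible translation, micrometres.
#' @param flag_threshold normalised objective above which the result is
#'   flagged low-confidence (for masks the normalised objective is
#'   `1 - Dice`).
#' @return an `auto_reg_params` list.
#' @export
auto_reg_params <- function(n_orientations_kept = 5L,
                            downsample_factors = c(6L, 4L, 2L),
                            angular_grid_step = 30,
                            angular_range = 180,
                            max_shift = Inf,
                            flag_threshold = 0.8) {
  downsample_factors <- as.integer(downsample_factors)
  if (is.unsorted(rev(downsample_factors)))
    stop("`downsample_factors` must be descending")
  if (n_orientations_kept < 1L) stop("`n_orientations_kept` must be >= 1")
  structure(list(n_orientations_kept = as.integer(n_orientations_kept),
                 downsample_factors = downsample_factors,
                 angular_grid_step = angular_grid_step,
                 angular_range = angular_range,
                 max_shift = max_shift,
                 flag_threshold = flag_threshold),
            class = "auto_reg_params")
}

# isotropic pyramid level: box smooth + stride subsample by integer factor
pyramid_level <- function(arr, spacing, f) {
  if (f <= 1L) return(list(arr = arr, spacing = spacing))
  box <- rep(1 / f, f)
  sm <- conv_sep3d_cpp(arr, box, box, box)
  d <- dim(arr)
  zi <- seq(1L, d[1], by = f); yi <- seq(1L, d[2], by = f)
  xi <- seq(1L, d[3], by = f)
  list(arr = sm[zi, yi, xi, drop = FALSE], spacing = spacing * f)
}

# best circular-correlation shift of m against t (same dims); returns
# list(shift_vox = c(z,y,x), score = max correlation sum)
best_shift_fft <- function(tv, mv, max_shift_vox) {
  ft <- stats::fft(tv); fm <- stats::fft(mv)
  cc <- Re(stats::fft(ft * Conj(fm), inverse = TRUE)) / length(tv)
  d <- dim(tv)
  wrap <- function(n) { v <- 0:(n - 1); v[v > n / 2] <- v[v > n / 2] - n; v }
  sz <- wrap(d[1]); sy <- wrap(d[2]); sx <- wrap(d[3])
  if (is.finite(max_shift_vox)) {
    okz <- abs(sz) <= max_shift_vox
    oky <- abs(sy) <= max_shift_vox
    okx <- abs(sx) <= max_shift_vox
    cc[!okz, , ] <- -Inf; cc[, !oky, ] <- -Inf; cc[, , !okx] <- -Inf
  }
  pk <- arrayInd(which.max(cc), d)
  list(shift_vox = c(sz[pk[1]], sy[pk[2]], sx[pk[3]]), score = max(cc))
}

#' Automatic rigid registration
#'
#' Registers `moving` onto `target` (typically segmented masks) by
#' squared-difference minimisation: an exhaustive Euler-angle grid search
#' at the coarsest pyramid level (translation solved per orientation by
#' FFT cross-correlation), keeping the `n_orientations_kept` best
#' candidates, each refined by Nelder-Mead over rotation and translation
#' through the finer pyramid levels. The rotation centre is the geometric
#' centre of the target volume.
#'
#' @param moving,target [binary_mask]s or [voxel_grid]s of identical
#'   spacing.
#' @param params an [auto_reg_params].
#' @return list with `transform` (a [rigid_transform]), `objective`
#'   (final sum of squared differences), `normalized_objective`
#'   (`SSD / (sum M^2 + sum T^2)`; equals `1 - Dice` for masks) and
#'   `low_confidence` (TRUE when no good alignment was found).
#' @export
register_automatic_rigid <- function(moving, target,
                                     params = auto_reg_params()) {
  mv_arr <- moving$data * 1.0; tv_arr <- target$data * 1.0
  if (sum(mv_arr != 0) == 0 || sum(tv_arr != 0) == 0)
    stop("empty moving or target image")
  if (max(abs(moving$spacing - target$spacing)) > 1e-9)
    stop("moving and target must share voxel spacing")
  sp <- target$spacing
  d <- dim(tv_arr)
  center <- c((d[3] - 1) / 2 * sp["x"], (d[2] - 1) / 2 * sp["y"],
              (d[1] - 1) / 2 * sp["z"])
  names(center) <- NULL

  factors <- params$downsample_factors
  f0 <- factors[1]
  lv_t <- pyramid_level(tv_arr, sp, f0)
  lv_m <- pyramid_level(mv_arr, sp, f0)
  tg0 <- voxel_grid(lv_t$arr, lv_t$spacing)
  mg0 <- voxel_grid(lv_m$arr, lv_m$spacing)

  # coarse orientation grid
  st <- params$angular_grid_step
  rng <- params$angular_range
  angs <- seq(-rng, rng - st, by = st)
  angs_half <- angs[angs > -90 - 1e-9 & angs <= 90 + 1e-9]  # pitch
  grid <- expand.grid(rz = angs, ry = angs_half, rx = angs)
  max_shift_vox <- params$max_shift / min(lv_t$spacing)

  score_one <- function(rz, ry, rx) {
    xf <- rigid_transform(euler_to_rotmat(rz, ry, rx), c(0, 0, 0), center)
    rot <- apply_rigid(mg0, xf, "linear", target = tg0)
    bs <- best_shift_fft(lv_t$arr, rot$data, max_shift_vox)
    ssd <- sum(rot$data^2) + sum(lv_t$arr^2) - 2 * bs$score * length(lv_t$arr)
    list(ssd = ssd, shift_vox = bs$shift_vox)
  }
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid)))
    res[[i]] <- score_one(grid$rz[i], grid$ry[i], grid$rx[i])
  ord <- order(vapply(res, function(r) r$ssd, numeric(1)))
  keep <- ord[seq_len(min(params$n_orientations_kept, length(ord)))]

  # refine candidates by Nelder-Mead through the finer levels
  max_shift <- params$max_shift
  refine_obj <- function(theta, mg, tg) {
    if (is.finite(max_shift) && any(abs(theta[4:6]) > max_shift))
      return(.Machine$double.xmax / 2)  # translation outside search range
    xf <- rigid_transform(euler_to_rotmat(theta[1], theta[2], theta[3]),
                          theta[4:6], center)
    rot <- apply_rigid(mg, xf, "linear", target = tg)
    sum((rot$data - tg$data)^2)
  }
  candidates <- lapply(keep, function(i) {
    sh <- res[[i]]$shift_vox * c(lv_t$spacing["z"], lv_t$spacing["y"],
                                 lv_t$spacing["x"])
    c(grid$rz[i], grid$ry[i], grid$rx[i], sh[3], sh[2], sh[1])
  })
  fine_factors <- factors[-1]
  if (length(fine_factors) == 0L) fine_factors <- factors[length(factors)]
  for (f in fine_factors) {
    lv_tf <- pyramid_level(tv_arr, sp, f)
    lv_mf <- pyramid_level(mv_arr, sp, f)
    tgf <- voxel_grid(lv_tf$arr, lv_tf$spacing)
    mgf <- voxel_grid(lv_mf$arr, lv_mf$spacing)
    vox <- min(lv_tf$spacing)
    candidates <- lapply(candidates, function(th) {
      o <- optim(th, refine_obj, mg = mgf, tg = tgf, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-7,
                                parscale = c(5, 5, 5, 2 * vox, 2 * vox,
                                             2 * vox)))
      structure(o$par, value = o$value)
    })
    vals <- vapply(candidates, function(th) attr(th, "value"), numeric(1))
    candidates <- candidates[order(vals)][
      seq_len(max(1L, ceiling(length(candidates) / 2)))]
  }
  best <- candidates[[1]]
  xf <- rigid_transform(euler_to_rotmat(best[1], best[2], best[3]),
                        best[4:6], center)
  # final objective at full resolution; for masks this makes the
  # normalised objective exactly 1 - Dice
  moved <- apply_rigid(moving, xf, target = target)
  obj <- sum((moved$data - target$data)^2)
  norm_obj <- obj / (sum(moved$data^2) + sum(target$data^2))
  list(transform = xf, objective = obj, normalized_objective = norm_obj,
       low_confidence = norm_obj > params$flag_threshold)
}

#' Population average map of co-registered masks
#'
#' Voxel-wise mean of binary masks brought into one coordinate system;
#' `mean_map * n_samples` is the per-voxel overlap count. High values mark
#' vessels conserved across the group.
#'
#' @param masks non-empty list of registered [binary_mask]s, same shape.
#' @param template_id identifier of the registration template.
#' @return object of class `population_average_map` with fields
#'   `mean_map`, `n_samples`, `template_id`, `spacing`.
#' @export
build_population_average_map <- function(masks, template_id = "template") {
  if (length(masks) < 1L) stop("`masks` must contain at least one mask")
  if (!all(vapply(masks, is_binary_mask, logical(1))))
    stop("all inputs must be binary_mask objects")
  d <- dim(masks[[1]]$data)
  if (!all(vapply(masks, function(m) identical(dim(m$data), d), logical(1))))
    stop("all masks must share the same shape")
  acc <- array(0, d)
  for (m in masks) acc <- acc + m$data
  structure(list(mean_map = acc / length(masks),
                 n_samples = length(masks),
                 template_id = template_id,
                 spacing = masks[[1]]$spacing),
            class = "population_average_map")
}

#' @export
print.population_average_map <- function(x, ...) {
  cat(sprintf("<population_average_map> n = %d, template '%s', mean foreground fraction %.4f\n",
              x$n_samples, x$template_id, mean(x$mean_map)))
  invisible(x)
}
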