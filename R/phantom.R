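# Synthetic 3D vascular phantoms with exact ground truth: straight/curved
# tubes, random bifurcating trees and bilaterally symmetric networks, plus
# a light-sheet-style intensity renderer (lumenised double-peak or solid
# single-peak cross-sections, PSF blur, Poisson-Gaussian noise).
#
# Geometry lives in voxel-index space (z, y, x), radii in voxels, so truth
# quantities (voxel counts, branch points, centerline length) are exact by
# construction; physical units follow from the declared spacing.

#' Phantom specification
#'
#' Defaults emulate the imaging regime of embryonic zebrafish brain
#' vasculature at light-sheet resolution: a 128 x 256 x 256 voxel volume
#' at 0.33 x 0.33 x 0.5 um spacing, so vessel diameters of 5-20 um map to
#' roughly 7-30 lateral voxels; lumenised vessels have ~1 um bright walls
#' around a dimmer lumen (double-peak cross-section), unlumenised vessels
#' are solid (single-peak). Noise is Poisson shot noise at a photon-scale
#' plus additive Gaussian read noise over a constant background.
#'
#' @param shape volume shape `(z, y, x)` in voxels.
#' @param spacing voxel size `(x, y, z)`, micrometres.
#' @param radius tube radius in voxels (single-tube phantoms).
#' @param n_bifurcations number of bifurcations for tree phantoms.
#' @param radius_range per-segment radius range (voxels) for trees.
#' @param segment_length_range segment length range (voxels).
#' @param branch_angle_range bifurcation half-angle range (degrees).
#' @param lumenised render double-peak (walled) cross-sections.
#' @param wall_thickness_um wall thickness for lumenised rendering.
#' @param vessel_peak,background,lumen_fraction intensity levels: wall/
#'   vessel peak, constant background, and lumen level as a fraction of
#'   the peak.
#' @param psf_sigma_um Gaussian PSF sigma (micrometres).
#' @param gaussian_sd additive read-noise standard deviation.
#' @param poisson_scale photons per intensity unit for shot noise (larger
#'   means less relative shot noise).
#' @param seed integer seed; required for randomised geometry.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(128L, 256L, 256L),
                         spacing = c(0.33, 0.33, 0.5),
                         radius = 4,
                         n_bifurcations = 5L,
                         radius_range = c(3, 7),
                         segment_length_range = c(35, 60),
                         branch_angle_range = c(20, 40),
                         lumenised = FALSE,
                         wall_thickness_um = 1,
                         vessel_peak = 200,
                         background = 20,
                         lumen_fraction = 0.35,
                         psf_sigma_um = 0.4,
                         gaussian_sd = 4,
                         poisson_scale = 0.5,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("shape must be positive")
  if (radius <= 0) stop("radius must be positive")
  if (vessel_peak < 0 || background < 0 || gaussian_sd < 0)
    stop("intensity parameters must be non-negative")
  structure(list(shape = shape, spacing = check_spacing(spacing),
                 radius = radius,
                 n_bifurcations = as.integer(n_bifurcations),
                 radius_range = radius_range,
                 segment_length_range = segment_length_range,
                 branch_angle_range = branch_angle_range,
                 lumenised = lumenised,
                 wall_thickness_um = wall_thickness_um,
                 vessel_peak = vessel_peak, background = background,
                 lumen_fraction = lumen_fraction,
                 psf_sigma_um = psf_sigma_um,
                 gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# evaluate expr with a private RNG stream; global .Random.seed restored
with_phantom_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# rasterize one tube segment into `arr` (modified copy returned):
# voxel included iff its centre lies within `radius` of the segment p0-p1
# (points and radius in voxel units, (z, y, x))
rasterize_segment <- function(arr, p0, p1, radius) {
  d <- dim(arr)
  lo <- pmax(floor(pmin(p0, p1) - radius), 0)
  hi <- pmin(ceiling(pmax(p0, p1) + radius), d - 1)
  if (any(lo > hi)) return(arr)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  v <- p1 - p0
  vv <- sum(v^2)
  zz <- array(rep(zi, times = length(yi) * length(xi)),
              c(length(zi), length(yi), length(xi)))
  yy <- array(rep(rep(yi, each = length(zi)), times = length(xi)),
              dim(zz))
  xx <- array(rep(xi, each = length(zi) * length(yi)), dim(zz))
  dz <- zz - p0[1]; dy <- yy - p0[2]; dx <- xx - p0[3]
  if (vv < 1e-12) {
    d2 <- dz^2 + dy^2 + dx^2
  } else {
    t <- pmin(pmax((dz * v[1] + dy * v[2] + dx * v[3]) / vv, 0), 1)
    d2 <- (dz - t * v[1])^2 + (dy - t * v[2])^2 + (dx - t * v[3])^2
  }
  blk <- arr[zi + 1L, yi + 1L, xi + 1L, drop = FALSE]
  blk[d2 <= radius^2] <- 1L
  arr[zi + 1L, yi + 1L, xi + 1L] <- blk
  arr
}

# centerline voxels of a polyline, sampled at quarter-voxel steps
centerline_voxels <- function(points) {
  out <- NULL
  for (i in seq_len(nrow(points) - 1L)) {
    p0 <- points[i, ]; p1 <- points[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    n <- max(2L, ceiling(len / 0.25))
    t <- seq(0, 1, length.out = n)
    seg <- cbind(p0[1] + t * (p1[1] - p0[1]),
                 p0[2] + t * (p1[2] - p0[2]),
                 p0[3] + t * (p1[3] - p0[3]))
    out <- rbind(out, round(seg))
  }
  unique(out)
}

#' Generate a single-tube phantom
#'
#' Rasterises a straight or curved tube (voxel centre within `radius` of
#' the centerline) and returns the mask together with analytically known
#' ground truth.
#'
#' @param spec a [phantom_spec].
#' @param control_points optional n x 3 matrix of centerline points
#'   `(z, y, x)` in voxels; default is a straight axis-aligned tube along
#'   y spanning 80% of the volume at mid-depth.
#' @return list with `mask` (a [binary_mask]) and `truth` (a
#'   `phantom_truth` list: `centerline_points`, `centerline_voxels`,
#'   `radius`, `branch_points` = empty, `branch_count` = 0,
#'   `length_voxels` (geometric centerline length), `volume_um3` (mask
#'   voxel count x voxel volume), `analytic_volume_voxels`
#'   (\eqn{\pi r^2 L}), `degenerate` flag for sub-voxel radii).
#' @export
generate_tube_phantom <- function(spec = phantom_spec(),
                                  control_points = NULL) {
  d <- spec$shape
  if (is.null(control_points)) {
    r0 <- ceiling(spec$radius)
    y0 <- max(round(0.1 * d[2]), r0 + 1)
    y1 <- min(round(0.9 * d[2]), d[2] - r0 - 2)
    # axis on the voxel lattice: even-width digital tubes (half-integer
    # axes) are degenerate for layer-by-layer thinning
    zc <- floor((d[1] - 1) / 2); xc <- floor((d[3] - 1) / 2)
    control_points <- rbind(c(zc, y0, xc), c(zc, y1, xc))
  }
  r <- spec$radius
  if (any(control_points - r < -0.5) ||
      any(sweep(control_points + r, 2, d - 0.5) > 0))
    stop("tube exceeds volume bounds")
  arr <- array(0L, d)
  for (i in seq_len(nrow(control_points) - 1L))
    arr <- rasterize_segment(arr, control_points[i, ],
                             control_points[i + 1L, ], r)
  degenerate <- r < 0.5
  cl <- centerline_voxels(control_points)
  if (degenerate) {  # sub-voxel radius: keep the stepped centerline itself
    arr[cl + 1L] <- 1L
  }
  mask <- binary_mask(arr, spec$spacing)
  seg_len <- sum(sqrt(rowSums(
    (control_points[-1, , drop = FALSE] -
       control_points[-nrow(control_points), , drop = FALSE])^2)))
  truth <- list(centerline_points = control_points,
                centerline_voxels = cl,
                radius = r,
                branch_points = matrix(numeric(0), 0, 3),
                branch_count = 0L,
                length_voxels = seg_len,
                volume_um3 = sum(arr) * voxel_volume(mask),
                analytic_volume_voxels = pi * r^2 * seg_len,
                degenerate = degenerate)
  class(truth) <- "phantom_truth"
  list(mask = mask, truth = truth)
}

# unit vector at `angle` degrees from `dir`, tilted within the plane
# spanned by `dir` and the azimuth `phi` (radians) around it; daughters of
# one bifurcation use opposed azimuths so they diverge in a common plane
tilt_direction <- function(dir, angle_deg, phi = runif(1, 0, 2 * pi)) {
  dir <- dir / sqrt(sum(dir^2))
  # orthonormal basis
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * dir) * dir
  u <- u / sqrt(sum(u^2))
  w <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  a <- angle_deg * pi / 180
  cos(a) * dir + sin(a) * (cos(phi) * u + sin(phi) * w)
}

# minimum surface clearance from sampled points `pts` to existing segment
# samples; `cloud` carries the local tube radius in column 4, so the
# returned value is centre distance minus the cloud tube's radius
min_dist_to_cloud <- function(pts, cloud) {
  if (is.null(cloud) || nrow(cloud) == 0L) return(Inf)
  mind <- Inf
  for (i in seq_len(nrow(pts))) {
    dd <- sqrt(rowSums(sweep(cloud[, 1:3, drop = FALSE], 2, pts[i, ])^2)) -
      cloud[, 4]
    mind <- min(mind, min(dd))
  }
  mind
}

#' Generate a random bifurcating-tree phantom
#'
#' Grows a binary tree of straight tube segments: starting from a trunk,
#' `spec$n_bifurcations` tips are split into two daughters with random
#' branch angles, lengths and tapered radii. Candidate daughters that
#' would leave the volume or collide with existing, non-adjacent segments
#' are resampled (bounded retries, then error), so the skeleton topology
#' of the mask matches the constructed tree exactly.
#'
#' @param spec a [phantom_spec].
#' @param seed overrides `spec$seed`.
#' @return list with `mask` and `truth` (`branch_points` and
#'   `branch_count` = number of bifurcations, `segments` with per-segment
#'   radii, `length_voxels` = total geometric centerline length,
#'   `centerline_voxels`, `volume_um3`).
#' @export
generate_tree_phantom <- function(spec = phantom_spec(), seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  # bounded whole-tree restarts with derived sub-seeds when the sampled
  # geometry cannot be placed collision-free inside the volume
  for (restart in 0:9) {
    out <- tryCatch(generate_tree_once(spec, seed + 7919L * restart),
                    error = function(e)
                      if (grepl("could not fit", conditionMessage(e))) NULL
                      else stop(e))
    if (!is.null(out)) return(out)
  }
  stop("could not fit the requested tree into the volume")
}

generate_tree_once <- function(spec, seed) {
  d <- spec$shape
  with_phantom_seed(seed, {
    margin <- max(spec$radius_range) + 2
    segments <- list()
    cloud <- NULL  # sampled points of accepted segments (with radius col)
    sample_len <- function() runif(1, spec$segment_length_range[1],
                                   spec$segment_length_range[2])
    sample_ang <- function() runif(1, spec$branch_angle_range[1],
                                   spec$branch_angle_range[2])
    seg_points <- function(p0, p1) {
      len <- sqrt(sum((p1 - p0)^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(len / 2)))
      cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]),
            p0[3] + t * (p1[3] - p0[3]))
    }
    in_bounds <- function(p, r)
      all(p - r >= 0.5) && all(p + r <= d - 1.5)
    root <- c((d[1] - 1) / 2, margin + 2, (d[3] - 1) / 2)
    dir0 <- c(0, 1, 0)
    r0 <- max(spec$radius_range)
    trunk_end <- root + sample_len() * dir0
    if (!in_bounds(trunk_end, r0)) trunk_end <- root + 30 * dir0
    segments[[1]] <- list(p0 = root, p1 = trunk_end, radius = r0)
    cloud <- cbind(seg_points(root, trunk_end), r0)
    tips <- list(list(pos = trunk_end, dir = dir0, radius = r0))
    branch_points <- NULL
    for (b in seq_len(spec$n_bifurcations)) {
      placed <- FALSE
      for (attempt in 1:200) {
        ti <- sample.int(length(tips), 1)
        tip <- tips[[ti]]
        r_child <- max(min(spec$radius_range),
                       tip$radius * runif(1, 0.8, 0.95))
        phi <- runif(1, 0, 2 * pi)
        d1 <- tilt_direction(tip$dir, sample_ang(), phi)
        d2 <- tilt_direction(tip$dir, sample_ang(), phi + pi)
        ok <- TRUE
        children <- list()
        for (dd in list(d1, d2)) {
          len <- sample_len()
          pend <- tip$pos + len * dd
          if (!in_bounds(pend, r_child)) { ok <- FALSE; break }
          pts <- seg_points(tip$pos, pend)
          # ignore samples near the shared junction when checking clearance
          far <- pts[sqrt(rowSums(sweep(pts, 2, tip$pos)^2)) >
                       3 * tip$radius, , drop = FALSE]
          if (nrow(far) > 0 &&
              min_dist_to_cloud(far, cloud) < r_child + 3) {
            ok <- FALSE; break
          }
          children[[length(children) + 1L]] <-
            list(p0 = tip$pos, p1 = pend, dir = dd, radius = r_child)
        }
        if (!ok || length(children) < 2L) next
        # accept
        for (ch in children) {
          segments[[length(segments) + 1L]] <-
            list(p0 = ch$p0, p1 = ch$p1, radius = ch$radius)
          cloud <- rbind(cloud, cbind(seg_points(ch$p0, ch$p1),
                                      ch$radius))
        }
        branch_points <- rbind(branch_points, tip$pos)
        tips[[ti]] <- NULL
        tips <- c(tips, list(list(pos = children[[1]]$p1,
                                  dir = children[[1]]$dir,
                                  radius = children[[1]]$radius),
                             list(pos = children[[2]]$p1,
                                  dir = children[[2]]$dir,
                                  radius = children[[2]]$radius)))
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not fit the requested tree into the volume")
    }
    arr <- array(0L, d)
    cl <- NULL
    total_len <- 0
    for (s in segments) {
      arr <- rasterize_segment(arr, s$p0, s$p1, s$radius)
      cl <- rbind(cl, centerline_voxels(rbind(s$p0, s$p1)))
      total_len <- total_len + sqrt(sum((s$p1 - s$p0)^2))
    }
    cl <- unique(cl)
    mask <- binary_mask(arr, spec$spacing)
    truth <- list(segments = segments,
                  centerline_voxels = cl,
                  branch_points = branch_points,
                  branch_count = spec$n_bifurcations,
                  length_voxels = total_len,
                  volume_um3 = sum(arr) * voxel_volume(mask),
                  degenerate = FALSE)
    class(truth) <- "phantom_truth"
    list(mask = mask, truth = truth)
  })
}

#' Generate a bilaterally symmetric phantom
#'
#' Grows one hemisphere tree strictly left of the midline voxel column and
#' reflects it across the midline plane (`x -> 2 * midline - x`), so the
#' mask equals its own mirror image exactly. Optional right-only segments
#' inject a known asymmetry whose exact voxel count is recorded.
#'
#' @param spec a [phantom_spec].
#' @param seed overrides `spec$seed`.
#' @param n_extra_right number of extra right-hemisphere-only segments.
#' @return list with `mask` and `truth` (adds `midline_x` and
#'   `asymmetry_voxels`, the foreground count present on the right only).
#' @export
generate_symmetric_phantom <- function(spec = phantom_spec(), seed = NULL,
                                       n_extra_right = 0L) {
  if (is.null(seed)) seed <- spec$seed
  d <- spec$shape
  mid <- d[3] %/% 2L  # midline voxel column, 0-based
  # grow the left tree in a narrowed volume [0, mid) and embed
  half_spec <- spec
  half_spec$shape <- c(d[1], d[2], mid)
  tree <- generate_tree_phantom(half_spec, seed = seed)
  arr <- array(0L, d)
  arr[, , 1:mid] <- tree$mask$data
  # reflect left onto right across column `mid`
  xs <- 0:(mid - 1L)
  xr <- 2L * mid - xs
  keep <- xr <= d[3] - 1L
  arr[, , xr[keep] + 1L] <- pmax(arr[, , xr[keep] + 1L, drop = FALSE],
                                 arr[, , xs[keep] + 1L, drop = FALSE])
  asym <- 0L
  if (n_extra_right > 0L) {
    with_phantom_seed(seed + 1L, {
      for (i in seq_len(n_extra_right)) {
        r <- min(spec$radius_range)
        z0 <- runif(1, r + 2, d[1] - r - 3)
        y0 <- runif(1, 0.2 * d[2], 0.6 * d[2])
        x0 <- runif(1, mid + r + 4, d[3] - r - 3)
        len <- runif(1, spec$segment_length_range[1],
                     spec$segment_length_range[2])
        y1 <- min(y0 + len, d[2] - r - 3)
        before <- sum(arr)
        arr <- rasterize_segment(arr, c(z0, y0, x0), c(z0, y1, x0), r)
        asym <- asym + sum(arr) - before
      }
    })
  }
  mask <- binary_mask(arr, spec$spacing)
  truth <- tree$truth
  truth$midline_x <- mid
  truth$asymmetry_voxels <- asym
  truth$volume_um3 <- sum(arr) * voxel_volume(mask)
  truth$branch_count <- tree$truth$branch_count  # per hemisphere
  list(mask = mask, truth = truth)
}

#' Render a noisy intensity volume from a phantom mask
#'
#' Builds the light-sheet-style intensity image of a vascular truth mask:
#' unlumenised mode paints solid tubes at `vessel_peak`; lumenised mode
#' paints a bright wall shell of `wall_thickness_um` and a dimmer lumen
#' (`lumen_fraction * vessel_peak`), giving the double-peak cross-section
#' of membrane-labelled lumenised vessels. The field is blurred by a
#' Gaussian PSF, then degraded by Poisson shot noise (scaled by
#' `poisson_scale` photons per intensity unit) and additive Gaussian read
#' noise over the constant `background`.
#'
#' @param mask truth [binary_mask].
#' @param spec a [phantom_spec] (intensity/noise parameters and seed).
#' @param seed overrides `spec$seed`.
#' @return an intensity [voxel_grid] (16-bit dynamic range).
#' @export
render_noisy <- function(mask, spec = phantom_spec(), seed = NULL) {
  stopifnot(is_binary_mask(mask))
  if (is.null(seed)) seed <- spec$seed
  sp <- mask$spacing
  img <- mask$data * spec$vessel_peak
  if (spec$lumenised) {
    edm <- euclidean_distance_map(mask, physical = TRUE)
    wall <- mask$data == 1L & edm$data <= spec$wall_thickness_um
    lumen <- mask$data == 1L & !wall
    img[wall] <- spec$vessel_peak
    img[lumen] <- spec$lumen_fraction * spec$vessel_peak
  }
  img <- img + spec$background
  if (spec$psf_sigma_um > 0) {
    sv <- c(spec$psf_sigma_um / sp[["z"]], spec$psf_sigma_um / sp[["y"]],
            spec$psf_sigma_um / sp[["x"]])
    img <- conv_sep3d_cpp(img, gauss_kernel(max(sv[1], 1e-3), 0L),
                          gauss_kernel(max(sv[2], 1e-3), 0L),
                          gauss_kernel(max(sv[3], 1e-3), 0L))
  }
  if (spec$poisson_scale > 0 || spec$gaussian_sd > 0) {
    img <- with_phantom_seed(seed, {
      out <- img
      if (spec$poisson_scale > 0)
        out <- rpois(length(img), lambda = pmax(img, 0) *
                       spec$poisson_scale) / spec$poisson_scale
      if (spec$gaussian_sd > 0)
        out <- out + rnorm(length(img), 0, spec$gaussian_sd)
      out
    })
  }
  img <- pmax(img, 0)
  dim(img) <- dim(mask$data)
  voxel_grid(img, mask$spacing, dtype_range = c(0, 65535))
}
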