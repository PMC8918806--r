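# Pre-processing and segmentation: slice-drift correction, multi-scale
# Sato tubular enhancement, Otsu thresholding.

#' Segmentation parameters
#'
#' @param scales_um vesselness scales (Gaussian sigma) in micrometres.
#'   The defaults `{1, 2, 4}` um cover vessel diameters of roughly 5-20 um
#'   after conversion to voxels via the grid spacing.
#' @param histogram_bins number of histogram bins for Otsu thresholding
#'   (256, matching 8-bit histogramming; 16-bit data are rebinned).
#' @param drift_max_shift maximum per-slice drift in pixels considered by
#'   [correct_slice_drift()].
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(scales_um = c(1, 2, 4), histogram_bins = 256L,
                                drift_max_shift = 20L) {
  scales_um <- as.numeric(scales_um)
  if (length(scales_um) < 1L || any(scales_um <= 0))
    stop("`scales_um` must be a non-empty vector of positive scales")
  histogram_bins <- as.integer(histogram_bins)
  if (histogram_bins < 2L) stop("`histogram_bins` must be at least 2")
  structure(list(scales_um = scales_um, histogram_bins = histogram_bins,
                 drift_max_shift = as.integer(drift_max_shift)),
            class = "segmentation_params")
}

# sampled Gaussian (derivative) kernel in voxel units; order 0, 1 or 2.
# The base Gaussian is normalised to unit sum; derivative kernels are
# forced to the exact discrete moment conditions (sum 0) so that the
# response is invariant to additive intensity offsets.
gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -x / sigma^2 * g
    return(k - mean(k))          # odd already; exact zero-sum
  }
  if (order == 2L) {
    k <- (x^2 / sigma^4 - 1 / sigma^2) * g
    return(k - mean(k))          # zero DC response
  }
  stop("unsupported derivative order")
}

# one Hessian component of `arr` at per-axis voxel sigmas; `orders` is the
# derivative order (z, y, x). Result is in voxel units.
hessian_component <- function(arr, sig_vox, orders) {
  conv_sep3d_cpp(arr,
                 gauss_kernel(sig_vox[1], orders[1]),
                 gauss_kernel(sig_vox[2], orders[2]),
                 gauss_kernel(sig_vox[3], orders[3]))
}

#' Multi-scale Sato vesselness (tubeness)
#'
#' Per-voxel tubeness from the eigenvalues of the Gaussian-scale Hessian.
#' With eigenvalues sorted \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3}, a
#' bright tubular structure has \eqn{\lambda_2, \lambda_3 \ll 0} and
#' \eqn{\lambda_1 \approx 0}; the response is
#' \eqn{\sqrt{\lambda_2 \lambda_3}} when both are negative and 0 otherwise
#' (the Sato line filter as implemented by the Fiji "Tubeness" plugin).
#' Multi-scale analysis takes the voxel-wise maximum over scales of the
#' \eqn{\sigma^2}-normalised responses (gamma = 1 scale normalisation).
#' Anisotropic spacing is handled by using a per-axis sigma in voxels,
#' `sigma_um / spacing_axis`.
#'
#' @param grid a [voxel_grid].
#' @param params a [segmentation_params] providing `scales_um`.
#' @return a [voxel_grid] of non-negative vesselness responses.
#' @references Sato et al. (1998) Medical Image Analysis 2(2):143-168.
#' @export
sato_vesselness <- function(grid, params = segmentation_params()) {
  stopifnot(is_voxel_grid(grid))
  if (!all(is.finite(grid$data))) stop("non-finite intensities")
  d <- dim(grid$data)
  if (any(d < 5L))
    stop("grid must have at least 5 voxels per axis for Hessian estimation")
  sp <- grid$spacing  # (x, y, z)
  best <- array(0, d)
  for (sigma in params$scales_um) {
    if (sigma < min(sp))
      warning(sprintf("scale %.3g um is below the smallest voxel spacing %.3g um",
                      sigma, min(sp)))
    # per-axis sigma in voxels, (z, y, x) order to match array axes
    sv <- c(sigma / sp["z"], sigma / sp["y"], sigma / sp["x"])
    # second derivatives in physical units: divide by spacing^order
    hzz <- hessian_component(grid$data, sv, c(2L, 0L, 0L)) / sp["z"]^2
    hyy <- hessian_component(grid$data, sv, c(0L, 2L, 0L)) / sp["y"]^2
    hxx <- hessian_component(grid$data, sv, c(0L, 0L, 2L)) / sp["x"]^2
    hzy <- hessian_component(grid$data, sv, c(1L, 1L, 0L)) / (sp["z"] * sp["y"])
    hzx <- hessian_component(grid$data, sv, c(1L, 0L, 1L)) / (sp["z"] * sp["x"])
    hyx <- hessian_component(grid$data, sv, c(0L, 1L, 1L)) / (sp["y"] * sp["x"])
    resp <- sigma^2 * tubeness_from_hessian_cpp(hzz, hyy, hxx, hzy, hzx, hyx)
    best <- pmax(best, resp)
  }
  dim(best) <- d
  voxel_grid(best, grid$spacing, dtype_range = range(best))
}

#' Otsu threshold of a volume
#'
#' Histogram-based threshold maximising the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2}; ties are broken towards the
#' lowest maximising bin and the mask applies a strict `>`. Integer data
#' whose level count fits `bins` are histogrammed at native levels (so the
#' result is exact for 8-bit data); wider-range data are rebinned to
#' `bins` equal-width bins.
#'
#' @param grid a [voxel_grid].
#' @param bins number of histogram bins.
#' @return list with `threshold` (intensity) and `mask` (a [binary_mask]
#'   of voxels strictly above the threshold).
#' @export
otsu_threshold <- function(grid, bins = 256L) {
  stopifnot(is_voxel_grid(grid))
  v <- as.vector(grid$data)
  if (length(unique(v)) < 2L)
    stop("degenerate histogram: image has fewer than 2 distinct values")
  integer_mode <- all(v >= 0) && all(v == floor(v)) && max(v) < bins
  if (integer_mode) {
    counts <- tabulate(as.integer(v) + 1L, nbins = as.integer(max(v)) + 1L)
    centers <- seq_along(counts) - 1
    thr_values <- centers[-length(centers)]       # split <= t / > t
  } else {
    lo <- min(v); hi <- max(v)
    breaks <- seq(lo, hi, length.out = bins + 1L)
    idx <- pmin(pmax(floor((v - lo) / (hi - lo) * bins) + 1L, 1L), bins)
    counts <- tabulate(idx, nbins = bins)
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
    thr_values <- breaks[2:bins]                  # inner bin boundaries
  }
  thr <- otsu_from_histogram(counts, centers, thr_values)
  m <- (grid$data > thr) * 1L
  dim(m) <- dim(grid$data)
  list(threshold = thr, mask = binary_mask(m, grid$spacing))
}

# maximise between-class variance over the candidate splits; candidate k
# separates bins [1..k] from [k+1..B]
otsu_from_histogram <- function(counts, centers, thr_values) {
  n <- sum(counts)
  p <- counts / n
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(counts) - 1L)
  w0k <- w0[k]; w1k <- 1 - w0k
  valid <- w0k > 0 & w1k > 0
  bcv <- rep(-Inf, length(k))
  bcv[valid] <- (mu_t * w0k[valid] - mu[k][valid])^2 /
    (w0k[valid] * w1k[valid])
  thr_values[which.max(bcv)]   # which.max takes the first (lowest) maximum
}

#' Correct lateral slice drift in a z-stack
#'
#' Aligns each z-slice to its predecessor by the 2D translation maximising
#' the phase correlation between the slices, then applies the cumulative
#' integer shift (acquisition jitter between light-sheet planes is
#' translational). Sub-pixel estimates come from a parabolic fit around the
#' correlation peak and are reported alongside the applied integer shifts.
#'
#' A shift is only trusted (and applied) when the phase-correlation peak
#' is decisive: slices whose content genuinely differs — as consecutive
#' optical planes legitimately do — produce diffuse correlation surfaces
#' whose spurious "shifts" would otherwise accumulate into a random walk.
#' The cumulative correction is additionally clamped to `max_shift`.
#'
#' @param grid a [voxel_grid] with at least 2 slices.
#' @param max_shift largest admissible cumulative shift in pixels.
#' @param min_peak phase-correlation peak height below which a slice pair
#'   is considered to carry no drift evidence (genuine translated
#'   duplicates peak near 1; unrelated content near 0).
#' @return list with `grid` (corrected volume), `shifts` (n_slices x 2
#'   matrix of cumulative applied `(dy, dx)` integer shifts), `peaks`
#'   (per-slice correlation peaks) and `degenerate` (TRUE when the stack
#'   carried no usable structure, in which case all shifts are zero).
#' @export
correct_slice_drift <- function(grid, max_shift = 20L, min_peak = 0.3) {
  stopifnot(is_voxel_grid(grid))
  d <- dim(grid$data)
  if (d[1] < 2L) stop("drift correction needs at least 2 slices")
  degenerate <- FALSE
  rel <- matrix(0, d[1], 2)
  peaks <- rep(NA_real_, d[1])
  for (k in 2:d[1]) {
    a <- grid$data[k - 1L, , , drop = TRUE]
    b <- grid$data[k, , , drop = TRUE]
    if (sd(a) == 0 || sd(b) == 0) {
      degenerate <- TRUE
      next
    }
    est <- phase_correlate_2d(a, b, max_shift)
    peaks[k] <- est$peak
    if (est$peak >= min_peak) rel[k, ] <- est$shift
  }
  cum <- apply(rel, 2, cumsum)
  cum <- pmin(pmax(cum, -max_shift), max_shift)
  applied <- round(cum)
  out <- grid$data
  for (k in 2:d[1])
    out[k, , ] <- shift_slice_int(grid$data[k, , , drop = TRUE],
                                  -applied[k, 1], -applied[k, 2])
  res <- list(grid = voxel_grid(out, grid$spacing,
                                dtype_range = grid$dtype_range),
              shifts = applied, shifts_subpixel = cum, peaks = peaks,
              degenerate = degenerate)
  if (degenerate) warning("constant slices: drift correction is a no-op")
  res
}

# translation (dy, dx) such that b ~ shift(a, by = (dy, dx));
# phase correlation with Hann-free plain normalisation, parabolic subpixel
phase_correlate_2d <- function(a, b, max_shift) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  cp <- fa * Conj(fb)
  mag <- Mod(cp)
  cp <- cp / pmax(mag, 1e-12)
  cc <- Re(stats::fft(cp, inverse = TRUE))
  ny <- nrow(a); nx <- ncol(a)
  # admissible circular shifts
  dy <- c(0:(ny - 1)); dy[dy > ny / 2] <- dy[dy > ny / 2] - ny
  dx <- c(0:(nx - 1)); dx[dx > nx / 2] <- dx[dx > nx / 2] - nx
  ok <- outer(abs(dy) <= max_shift, abs(dx) <= max_shift)
  cc[!ok] <- -Inf
  pk <- arrayInd(which.max(cc), dim(cc))
  py <- pk[1]; px <- pk[2]
  sub <- function(cvec, i, n) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    den <- cvec[im] - 2 * cvec[i] + cvec[ip]
    if (!is.finite(den) || den == 0) return(0)
    delta <- 0.5 * (cvec[im] - cvec[ip]) / den
    max(min(delta, 0.5), -0.5)
  }
  oy <- sub(cc[, px], py, ny)
  ox <- sub(cc[py, ], px, nx)
  shift <- c(dy[py] + oy, dx[px] + ox)
  # fft convention: peak at index of (a shifted onto b); sign gives b = a
  # shifted by -shift, so drift of b relative to a is -shift
  list(shift = -shift, peak = max(cc) / (ny * nx))
}

# integer shift with zero fill
shift_slice_int <- function(s, dy, dx) {
  ny <- nrow(s); nx <- ncol(s)
  out <- matrix(0, ny, nx)
  ys <- intersect(seq_len(ny), seq_len(ny) - dy)
  xs <- intersect(seq_len(nx), seq_len(nx) - dx)
  out[ys + dy, xs + dx] <- s[ys, xs]
  out
}

#' Segment the vasculature of a raw volume
#'
#' Full segmentation stage: optional slice-drift correction, multi-scale
#' Sato vesselness enhancement, then Otsu thresholding of the enhanced
#' volume.
#'
#' @param grid raw intensity [voxel_grid].
#' @param params a [segmentation_params].
#' @param drift_correction apply [correct_slice_drift()] first.
#' @return a [binary_mask] on the input geometry, with attributes
#'   `threshold` (the Otsu cut on the enhanced image) and `shifts` (the
#'   applied per-slice drift, when enabled).
#' @export
segment_vasculature <- function(grid, params = segmentation_params(),
                                drift_correction = TRUE) {
  stopifnot(is_voxel_grid(grid))
  shifts <- NULL
  if (drift_correction && dim(grid$data)[1] >= 2L) {
    dc <- suppressWarnings(correct_slice_drift(grid, params$drift_max_shift))
    grid <- dc$grid
    shifts <- dc$shifts
  }
  enh <- sato_vesselness(grid, params)
  seg <- otsu_threshold(enh, params$histogram_bins)
  mask <- seg$mask
  attr(mask, "threshold") <- seg$threshold
  attr(mask, "shifts") <- shifts
  mask
}
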