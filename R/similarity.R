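# Similarity assessment between a moving image M and a target image T:
# overlap metrics on binary masks (Dice, Jaccard, total overlap) and
# intensity metrics (mutual information, SSD, MSE, SSIM).

#' Overlap metrics between two binary masks
#'
#' Dice coefficient `DC = 2|M∩T| / (|M| + |T|)`, Jaccard index
#' `JI = |M∩T| / |M∪T|` and total overlap `TO = |M∩T| / |T|` with the
#' second argument `T` as the target/reference (TO is therefore not
#' symmetric; DC and JI are).
#'
#' @param M,T [binary_mask]s of identical shape (moving, target).
#' @return list with `dice`, `jaccard`, `total_overlap` and `degenerate`
#'   (TRUE when both masks are empty, in which case DC and JI are defined
#'   as 0, or when `T` is empty, in which case TO is `NA`).
#' @export
binary_overlap_metrics <- function(M, T) {
  stopifnot(is_binary_mask(M), is_binary_mask(T))
  if (!identical(dim(M$data), dim(T$data))) stop("shape mismatch")
  nM <- sum(M$data); nT <- sum(T$data)
  nMT <- sum(M$data & T$data)
  degenerate <- FALSE
  if (nM + nT == 0) {
    dice <- 0; jac <- 0; degenerate <- TRUE
  } else {
    dice <- 2 * nMT / (nM + nT)
    jac <- nMT / (nM + nT - nMT)
  }
  if (nT == 0) {
    to <- NA_real_; degenerate <- TRUE
  } else {
    to <- nMT / nT
  }
  list(dice = dice, jaccard = jac, total_overlap = to,
       degenerate = degenerate)
}

#' Intensity similarity metrics between two volumes
#'
#' Mutual information from the joint histogram (base-2 logarithm, so the
#' result is in bits), sum of squared differences `SSD = sum((M - T)^2)`,
#' mean square error `MSE = SSD / N`, and mean structural similarity
#' (SSIM, Wang et al. 2004) computed slice-wise on z-slices with a
#' Gaussian window (sigma 1.5, constants K1 = 0.01, K2 = 0.03) and
#' averaged.
#'
#' Mutual information uses a 64-bin joint histogram on min-max normalised
#' intensities; binary images use the exact 2x2 contingency table. For
#' identical images MI equals the marginal entropy H(T).
#'
#' @param M,T [voxel_grid]s or [binary_mask]s of identical shape.
#' @param mi_bins joint-histogram bins for continuous data.
#' @param dynamic_range SSIM dynamic range `L`; defaults to the target's
#'   `dtype_range` width (1 for masks).
#' @return list with `mutual_information`, `ssd`, `mse`, `ssim` and
#'   `flags` (character vector, e.g. zero-variance input for SSIM).
#' @export
intensity_similarity_metrics <- function(M, T, mi_bins = 64L,
                                         dynamic_range = NULL) {
  a <- M$data * 1.0; b <- T$data * 1.0
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  flags <- character(0)
  ssd <- sum((a - b)^2)
  mse <- ssd / length(a)
  mi <- mutual_information(a, b, mi_bins)
  if (is.null(dynamic_range)) {
    dynamic_range <- if (is_voxel_grid(T)) diff(T$dtype_range) else 1
    if (!is.finite(dynamic_range) || dynamic_range <= 0) dynamic_range <- 1
  }
  if (sd(a) == 0 || sd(b) == 0)
    flags <- c(flags, "zero-variance image: SSIM is ill-conditioned")
  ssim <- ssim_volume(a, b, dynamic_range)
  list(mutual_information = mi, ssd = ssd, mse = mse, ssim = ssim,
       flags = flags)
}

# base-2 mutual information from a joint histogram
mutual_information <- function(a, b, bins = 64L) {
  av <- as.vector(a); bv <- as.vector(b)
  binarize <- function(v) all(v %in% c(0, 1))
  if (binarize(av) && binarize(bv)) {
    ia <- as.integer(av) + 1L; ib <- as.integer(bv) + 1L
    joint <- matrix(tabulate((ia - 1L) * 2L + ib, nbins = 4L), 2, 2)
  } else {
    cut_idx <- function(v) {
      lo <- min(v); hi <- max(v)
      if (hi == lo) return(rep(1L, length(v)))
      pmin(pmax(floor((v - lo) / (hi - lo) * bins) + 1L, 1L), bins)
    }
    ia <- cut_idx(av); ib <- cut_idx(bv)
    joint <- matrix(tabulate((ia - 1L) * bins + ib, nbins = bins * bins),
                    bins, bins)
  }
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

# mean SSIM over z-slices, Gaussian window sigma 1.5
ssim_volume <- function(a, b, L, K1 = 0.01, K2 = 0.03, win_sigma = 1.5) {
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  g <- gauss_kernel(win_sigma, 0L)
  kz <- 1  # no smoothing across z: slice-wise formulation
  mu_a <- conv_sep3d_cpp(a, kz, g, g)
  mu_b <- conv_sep3d_cpp(b, kz, g, g)
  mu_a2 <- mu_a^2; mu_b2 <- mu_b^2; mu_ab <- mu_a * mu_b
  s_a2 <- conv_sep3d_cpp(a * a, kz, g, g) - mu_a2
  s_b2 <- conv_sep3d_cpp(b * b, kz, g, g) - mu_b2
  s_ab <- conv_sep3d_cpp(a * b, kz, g, g) - mu_ab
  num <- (2 * mu_ab + C1) * (2 * s_ab + C2)
  den <- (mu_a2 + mu_b2 + C1) * (s_a2 + s_b2 + C2)
  mean(num / den)
}

#' Full similarity report between two images
#'
#' Convenience wrapper computing all seven similarity metrics; masks get
#' the overlap metrics, everything gets the intensity metrics.
#'
#' @param M,T two [binary_mask]s or [voxel_grid]s of identical shape.
#' @param ... passed to [intensity_similarity_metrics()].
#' @return a `similarity_report` list with fields `dice`, `jaccard`,
#'   `total_overlap` (NA for non-mask input), `mutual_information`,
#'   `ssd`, `mse`, `ssim`.
#' @export
similarity_report <- function(M, T, ...) {
  rep_int <- intensity_similarity_metrics(M, T, ...)
  if (is_binary_mask(M) && is_binary_mask(T)) {
    rep_bin <- binary_overlap_metrics(M, T)
  } else {
    rep_bin <- list(dice = NA_real_, jaccard = NA_real_,
                    total_overlap = NA_real_, degenerate = FALSE)
  }
  structure(list(dice = rep_bin$dice, jaccard = rep_bin$jaccard,
                 total_overlap = rep_bin$total_overlap,
                 mutual_information = rep_int$mutual_information,
                 ssd = rep_int$ssd, mse = rep_int$mse,
                 ssim = rep_int$ssim,
                 flags = rep_int$flags,
                 degenerate = rep_bin$degenerate),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report>\n")
  for (k in c("dice", "jaccard", "total_overlap", "mutual_information",
              "ssd", "mse", "ssim"))
    cat(sprintf("  %-18s %.6g\n", k, x[[k]]))
  invisible(x)
}
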