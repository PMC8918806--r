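# The eight-parameter vascular quantification stack: volume, surface,
# density, Euclidean distance map, 3D-thinning skeleton, network length,
# branch points, vessel radius (skeletonised distance map) and Sholl
# complexity.

#' Vascular volume in a region of interest
#'
#' Foreground voxel count inside the ROI multiplied by the physical voxel
#' volume.
#'
#' @param mask a [binary_mask].
#' @param roi a [roi_box]; defaults to the full extent.
#' @return volume in cubic micrometres.
#' @export
vascular_volume <- function(mask, roi = full_roi(mask)) {
  stopifnot(is_binary_mask(mask))
  sub <- crop_to_roi(mask, roi)
  sum(sub$data) * voxel_volume(mask)
}

#' Surface voxels of the vascular mask
#'
#' A foreground voxel is a surface voxel when at least one of its six
#' face-connected neighbours is background (voxels outside the grid count
#' as background). The scaled variant multiplies the count by the voxel
#' volume, mirroring the volume-style scaling used for the surface
#' parameter A_n.
#'
#' @param mask a [binary_mask].
#' @param roi a [roi_box].
#' @return list with `count` and `surface_um3` (count x voxel volume).
#' @export
surface_voxels <- function(mask, roi = full_roi(mask)) {
  stopifnot(is_binary_mask(mask))
  sub <- crop_to_roi(mask, roi)$data
  d <- dim(sub)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- sub
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  nb_min <- pmin(pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE],
                 pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE],
                 pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1), drop = FALSE],
                 pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1), drop = FALSE],
                 pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3], drop = FALSE],
                 pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2), drop = FALSE])
  count <- sum(core == 1L & nb_min == 0L)
  list(count = count, surface_um3 = count * voxel_volume(mask))
}

#' Vascular density within a region of interest
#'
#' Vascular volume as a proportion of the total ROI volume,
#' `D = V_vessel / V_roi`, in `[0, 1]`.
#'
#' @inheritParams vascular_volume
#' @export
vascular_density <- function(mask, roi = full_roi(mask)) {
  stopifnot(is_binary_mask(mask))
  n_roi <- prod(roi$hi - roi$lo)
  if (n_roi == 0) stop("empty ROI")
  sub <- crop_to_roi(mask, roi)
  sum(sub$data) / n_roi
}

#' Euclidean distance map of a vascular mask
#'
#' For every foreground voxel, the exact Euclidean distance to the nearest
#' background voxel (0 on background). Distances are in voxel units by
#' default, matching pixel-based distance-map plugins; `physical = TRUE`
#' weights each axis by the voxel spacing and returns micrometres (useful
#' when lateral downsampling has made the grid anisotropic).
#'
#' @param mask a [binary_mask] containing at least one background voxel.
#' @param physical use physical spacing weights.
#' @return a [voxel_grid] of distances.
#' @export
euclidean_distance_map <- function(mask, physical = FALSE) {
  stopifnot(is_binary_mask(mask))
  if (all(mask$data == 1L)) stop("all-foreground mask has no background")
  w <- if (physical) mask$spacing[c("z", "y", "x")] else c(1, 1, 1)
  d2 <- edt3d_cpp(mask$data, w[1], w[2], w[3])
  voxel_grid(sqrt(d2), mask$spacing)
}

#' 3D skeletonisation by homotopic thinning
#'
#' Reduces the mask to a one-voxel-wide centreline by layer-by-layer
#' removal of border voxels, cycling over the six face directions so the
#' object erodes symmetrically and the skeleton stays medial. A voxel is
#' only removed when it is a simple point (removal preserves both
#' foreground 26-connectivity and background 6-connectivity) and not a
#' curve endpoint, and deletions within a peel are applied sequentially
#' with the simple-point test re-checked, so the number of 26-connected
#' foreground components is exactly preserved.
#'
#' Thinning of thick, blunt-ended tubes can leave short terminal spurs;
#' `prune_spurs_below` removes terminal branches shorter than the given
#' length (in voxels) when they attach to a junction.
#'
#' @param mask a [binary_mask].
#' @param prune_spurs_below prune terminal branches strictly shorter than
#'   this many voxels (0 disables pruning).
#' @return a [binary_mask] skeleton.
#' @export
skeletonize_3d <- function(mask, prune_spurs_below = 0) {
  stopifnot(is_binary_mask(mask))
  if (sum(mask$data) == 0L) return(mask)
  sk <- thin3d_cpp(mask$data)
  out <- binary_mask(sk, mask$spacing)
  if (prune_spurs_below > 0) {
    # pruning can leave redundant corner voxels behind, so re-thin to a
    # fixpoint and re-prune until stable
    for (pass in 1:4) {
      before <- sum(out$data)
      out <- prune_spurs(out, prune_spurs_below)
      out <- binary_mask(thin3d_cpp(out$data), mask$spacing)
      if (sum(out$data) == before) break
    }
  }
  out
}

# remove terminal skeleton branches shorter than `min_len` voxels that end
# at a junction (never removes isolated paths or whole components)
prune_spurs <- function(skeleton, min_len) {
  repeat {
    vox <- which(skeleton$data == 1L)
    if (length(vox) == 0L) return(skeleton)
    nc <- neighbor_count26_cpp(skeleton$data)
    ends <- which(skeleton$data == 1L & nc == 1L)
    removed_any <- FALSE
    d <- dim(skeleton$data)
    for (e in ends) {
      path <- walk_from_endpoint(skeleton$data, nc, e, d, max_len = min_len)
      if (!is.null(path$junction) && length(path$voxels) < min_len) {
        skeleton$data[path$voxels] <- 0L
        removed_any <- TRUE
        nc <- neighbor_count26_cpp(skeleton$data)
      }
    }
    if (!removed_any) return(skeleton)
  }
}

# follow a degree-<=2 chain from an endpoint until a junction (neighbour
# count >= 3) or another endpoint; returns voxels of the chain (junction
# excluded)
walk_from_endpoint <- function(skel, nc, start, d, max_len) {
  idx2zyx <- function(i) {
    i0 <- i - 1L
    c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
  }
  zyx2idx <- function(p) 1L + p[1] + d[1] * (p[2] + d[2] * p[3])
  path <- integer(0)
  prev <- -1L
  cur <- start
  while (length(path) <= max_len) {
    path <- c(path, cur)
    p <- idx2zyx(cur)
    nbrs <- integer(0)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dz == 0 && dy == 0 && dx == 0) next
      q <- p + c(dz, dy, dx)
      if (any(q < 0) || any(q >= d)) next
      j <- zyx2idx(q)
      if (skel[j] == 1L && j != prev) nbrs <- c(nbrs, j)
    }
    nbrs <- setdiff(nbrs, path)
    if (length(nbrs) == 0L) return(list(voxels = path, junction = NULL))
    nxt <- nbrs[1]
    if (nc[nxt] >= 3L) return(list(voxels = path, junction = nxt))
    prev <- cur
    cur <- nxt
  }
  list(voxels = path, junction = NULL)  # too long: not a spur
}

#' Total network length of a skeleton
#'
#' The primary definition is the skeleton voxel count (the histogram-based
#' centreline-voxel count used by the Fiji workflow). The calibrated
#' variant measures curve length: the skeleton's 26-adjacency graph is
#' reduced to its minimum spanning forest (dropping the redundant shortcut
#' edges that 26-adjacency induces along staircase paths), decomposed into
#' chains between junctions and endpoints, and each chain is measured as a
#' polyline subsampled every third voxel, which suppresses the systematic
#' staircase overestimate of raw step sums while following curvature. On
#' anastomotic loops the spanning forest omits one edge per cycle, so
#' looped networks are slightly underestimated.
#'
#' @param skeleton a [binary_mask] skeleton.
#' @return list with `length_voxels` (primary), `length_steps` (calibrated
#'   curve length in voxel units) and `length_um` (calibrated, spacing
#'   weighted).
#' @export
network_length <- function(skeleton) {
  stopifnot(is_binary_mask(skeleton))
  nvox <- sum(skeleton$data)
  if (nvox == 0L)
    return(list(length_voxels = 0L, length_steps = 0, length_um = 0))
  sp <- skeleton$spacing
  ed <- skeleton_edges(skeleton$data)
  if (nrow(ed) == 0L)
    return(list(length_voxels = nvox, length_steps = 0, length_um = 0))
  w_um <- sqrt((ed[, "dz"] * sp[["z"]])^2 + (ed[, "dy"] * sp[["y"]])^2 +
                 (ed[, "dx"] * sp[["x"]])^2)
  g <- igraph::graph_from_edgelist(cbind(as.character(ed[, "a"]),
                                         as.character(ed[, "b"])),
                                   directed = FALSE)
  mst <- igraph::mst(g, weights = w_um)
  chains <- tree_chains(mst)
  d <- dim(skeleton$data)
  lv <- 0; lu <- 0
  for (ch in chains) {
    vox <- as.numeric(ch)
    pts <- arrayInd(vox, d)  # (z, y, x), 1-based; offsets cancel in diffs
    sel <- unique(c(seq(1L, nrow(pts), by = 3L), nrow(pts)))
    pp <- pts[sel, , drop = FALSE]
    dp <- diff(pp)
    lv <- lv + sum(sqrt(rowSums(dp^2)))
    lu <- lu + sum(sqrt((dp[, 1] * sp[["z"]])^2 + (dp[, 2] * sp[["y"]])^2 +
                          (dp[, 3] * sp[["x"]])^2))
  }
  list(length_voxels = nvox, length_steps = lv, length_um = lu)
}

# decompose a forest graph into maximal chains whose interior vertices
# have degree 2; returns a list of vertex-name vectors (chain order)
tree_chains <- function(g) {
  deg <- igraph::degree(g)
  nodes <- names(deg)[deg != 2L]
  visited_edge <- logical(igraph::ecount(g))
  adj <- igraph::as_adj_list(g)
  inc <- igraph::as_adj_edge_list(g)
  vname <- igraph::V(g)$name
  chains <- list()
  walk <- function(v_id, e_id) {
    chain <- v_id
    cur <- v_id
    edge <- e_id
    repeat {
      visited_edge[edge] <<- TRUE
      ends <- igraph::ends(g, edge, names = FALSE)
      nxt <- if (ends[1] == cur) ends[2] else ends[1]
      chain <- c(chain, nxt)
      cur <- nxt
      if (deg[cur] != 2L) break
      es <- as.integer(inc[[cur]])
      edge <- es[!visited_edge[es]][1]
      if (is.na(edge)) break
    }
    chain
  }
  for (v in nodes) {
    v_id <- match(v, vname)
    for (e in as.integer(inc[[v_id]])) {
      if (visited_edge[e]) next
      chains[[length(chains) + 1L]] <- vname[walk(v_id, e)]
    }
  }
  # pure cycles (all-degree-2 components) are left; walk any unvisited edge
  for (e in seq_len(igraph::ecount(g))) {
    if (visited_edge[e]) next
    v_id <- igraph::ends(g, e, names = FALSE)[1]
    chains[[length(chains) + 1L]] <- vname[walk(v_id, e)]
  }
  chains
}

# edge list of the 26-adjacency graph over foreground voxels:
# columns a, b (linear indices) and the step offset (dz, dy, dx)
skeleton_edges <- function(skel) {
  d <- dim(skel)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, -1, 0),
                c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  vox <- which(skel == 1L)
  idx <- arrayInd(vox, d)
  out <- NULL
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    nb <- idx[, 1] + o[1] >= 1 & idx[, 1] + o[1] <= d[1] &
      idx[, 2] + o[2] >= 1 & idx[, 2] + o[2] <= d[2] &
      idx[, 3] + o[3] >= 1 & idx[, 3] + o[3] <= d[3]
    if (!any(nb)) next
    tgt <- (idx[nb, 1] + o[1]) +
      d[1] * ((idx[nb, 2] + o[2] - 1L) + d[2] * (idx[nb, 3] + o[3] - 1L))
    hit <- skel[tgt] == 1L
    if (!any(hit)) next
    out <- rbind(out, cbind(a = vox[nb][hit], b = tgt[hit],
                            dz = o[1], dy = o[2], dx = o[3]))
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 5,
                                  dimnames = list(NULL,
                                                  c("a", "b", "dz", "dy",
                                                    "dx")))
  out
}

#' Count skeleton branch points
#'
#' Junction voxels are skeleton voxels with three or more 26-connected
#' skeleton neighbours. At thick junctions several junction voxels touch;
#' 26-adjacent junction voxels are merged into one cluster and each
#' cluster counts as a single branching point (the raw voxel count is also
#' reported). A thick bifurcation can additionally split into nearby but
#' non-touching clusters inside one junction complex; when the distance
#' map of the source mask is supplied, clusters closer to each other than
#' the local vessel diameter are merged as well.
#'
#' @param skeleton a [binary_mask] skeleton.
#' @param edm optional [voxel_grid] distance map of the mask the skeleton
#'   came from (voxel units), enabling diameter-based junction merging.
#' @return list with `branch_points` (clustered count), `junction_voxels`
#'   (raw count) and `junction_mask`.
#' @export
count_branch_points <- function(skeleton, edm = NULL) {
  stopifnot(is_binary_mask(skeleton))
  nc <- neighbor_count26_cpp(skeleton$data)
  jn <- (skeleton$data == 1L & nc >= 3L) * 1L
  dim(jn) <- dim(skeleton$data)
  raw <- sum(jn)
  if (raw == 0L)
    return(list(branch_points = 0L, junction_voxels = 0L,
                junction_mask = binary_mask(jn, skeleton$spacing)))
  lab <- label3d_cpp(jn, 26L)
  n_cl <- max(lab)
  if (!is.null(edm) && n_cl > 1L) {
    d <- dim(jn)
    vox <- which(jn == 1L)
    cl_id <- lab[vox]
    pts <- arrayInd(vox, d)
    r_loc <- edm$data[vox]
    # single-linkage merge of clusters within the local vessel diameter
    parent <- seq_len(n_cl)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_len(n_cl - 1L)) for (b in (a + 1L):n_cl) {
      pa <- pts[cl_id == a, , drop = FALSE]
      pb <- pts[cl_id == b, , drop = FALSE]
      ra <- max(r_loc[cl_id == a]); rb <- max(r_loc[cl_id == b])
      thr <- max(2 * ra, 2 * rb)
      mind <- Inf
      for (i in seq_len(nrow(pa)))
        mind <- min(mind, sqrt(min(rowSums(sweep(pb, 2, pa[i, ])^2))))
      if (mind < thr) {
        ra_ <- find(a); rb_ <- find(b)
        if (ra_ != rb_) parent[rb_] <- ra_
      }
    }
    n_cl <- length(unique(vapply(seq_len(n_cl), find, integer(1))))
  }
  list(branch_points = n_cl, junction_voxels = raw,
       junction_mask = binary_mask(jn, skeleton$spacing))
}

#' Mean vessel radius from the skeletonised distance map
#'
#' The distance map is sampled along the skeleton (the skeletonised
#' distance map, SDM = EDM x skeleton): each skeleton voxel's value is the
#' local vessel radius, and the mean over skeleton voxels is the mean
#' vessel radius.
#'
#' @param edm distance-map [voxel_grid] from [euclidean_distance_map()].
#' @param skeleton a [binary_mask] skeleton of the same shape.
#' @return list with `mean_radius` (units of the EDM: voxels by default),
#'   `sdm` (the skeletonised distance map as a [voxel_grid]) and
#'   `n_samples`.
#' @export
mean_vessel_radius <- function(edm, skeleton) {
  stopifnot(is_voxel_grid(edm), is_binary_mask(skeleton))
  if (!identical(dim(edm$data), dim(skeleton$data))) stop("shape mismatch")
  if (sum(skeleton$data) == 0L) stop("empty skeleton")
  sdm <- edm$data * skeleton$data
  vals <- sdm[skeleton$data == 1L]
  list(mean_radius = mean(vals),
       sdm = voxel_grid(sdm, edm$spacing), n_samples = length(vals))
}

#' Sholl intersection profile of a skeleton projection
#'
#' Counts, for concentric circles of increasing radius around a centre
#' point on the 2D maximum-intensity projection of the skeleton, the
#' number of distinct crossings: each circle is sampled densely in angle
#' and the number of connected angular runs of foreground is the
#' intersection count at that radius. Defaults follow the workflow's
#' settings: 700-voxel maximum radius with a 5-voxel shell step.
#'
#' @param skeleton_mip 2D 0/1 matrix `(y, x)` (e.g.
#'   `max_intensity_projection(skeleton)`).
#' @param center `(y, x)` centre in 0-based pixel coordinates (placed at
#'   an anatomical reference such as the basilar-artery junction in the
#'   real workflow).
#' @param max_radius largest shell radius, pixels.
#' @param step shell spacing, pixels.
#' @return a `sholl_profile`: list with `radii`, `intersections`,
#'   `center`, `step`, `max_radius`, and `sum` (total intersections, the
#'   scalar complexity readout).
#' @export
sholl_profile <- function(skeleton_mip, center, max_radius = 700, step = 5) {
  if (step <= 0) stop("`step` must be positive")
  d <- dim(skeleton_mip)
  if (center[1] < 0 || center[1] > d[1] - 1 ||
      center[2] < 0 || center[2] > d[2] - 1)
    stop("centre outside image")
  radii <- seq(step, max_radius, by = step)
  counts <- integer(length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    n_theta <- max(64L, ceiling(2 * pi * r / 0.3))
    theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
    py <- round(center[1] + r * sin(theta))
    px <- round(center[2] + r * cos(theta))
    inside <- py >= 0 & py < d[1] & px >= 0 & px < d[2]
    fg <- logical(n_theta)
    fg[inside] <- skeleton_mip[cbind(py[inside] + 1L, px[inside] + 1L)] > 0
    counts[i] <- count_circular_runs(fg)
  }
  structure(list(radii = radii, intersections = counts,
                 center = as.numeric(center), step = step,
                 max_radius = max_radius, sum = sum(counts)),
            class = "sholl_profile")
}

# number of connected TRUE runs in a circular boolean sequence
count_circular_runs <- function(fg) {
  if (!any(fg)) return(0L)
  if (all(fg)) return(1L)
  sum(fg & !c(fg[length(fg)], fg[-length(fg)]))
}

#' @export
print.sholl_profile <- function(x, ...) {
  cat(sprintf("<sholl_profile> %d shells, step %g px, total intersections %d\n",
              length(x$radii), x$step, x$sum))
  invisible(x)
}

#' Quantify a vascular region: the eight-parameter record
#'
#' Runs the full morphometry stack on a segmented mask within an ROI.
#' Volume, surface and density are computed at full resolution; the mask
#' is then laterally downsampled (bilinear, to `downsample_to` pixels when
#' wider) before the distance-map, skeleton, length, branch-point, radius
#' and Sholl stages, which dominate processing cost. Dice similarity to a
#' registered template mask is included when one is supplied.
#'
#' @param mask segmented [binary_mask].
#' @param roi a [roi_box]; defaults to the full extent.
#' @param template_mask optional registered template [binary_mask] (same
#'   geometry as `mask`) for the Dice similarity S_n.
#' @param sample_id identifier recorded in the output row.
#' @param sholl_center optional `(y, x)` Sholl centre on the downsampled
#'   MIP; defaults to the skeleton centroid.
#' @param sholl_max_radius,sholl_step Sholl shell settings (pixels).
#' @param downsample_to lateral target size before the skeleton stages;
#'   `NULL` disables downsampling.
#' @param prune_spurs_below spur-pruning threshold passed to
#'   [skeletonize_3d()]; the default removes terminal spurs shorter than
#'   the mean local radius would produce from blunt tube ends.
#' @return a `metrics_record`: one-row data.frame with columns
#'   `sample_id, volume_um3, surface_voxels, surface_um3, density,
#'   length_voxels, length_um, branch_points, junction_voxels,
#'   mean_radius_voxels, mean_radius_um, sholl_sum, sholl_max,
#'   dice_to_template`; the full [sholl_profile] is attached as attribute
#'   `"sholl"`.
#' @export
quantify_region <- function(mask, roi = full_roi(mask),
                            template_mask = NULL, sample_id = "sample",
                            sholl_center = NULL, sholl_max_radius = 700,
                            sholl_step = 5, downsample_to = 512L,
                            prune_spurs_below = NULL) {
  stopifnot(is_binary_mask(mask))
  sub <- crop_to_roi(mask, roi)

  vol <- vascular_volume(mask, roi)
  surf <- surface_voxels(mask, roi)
  dens <- vascular_density(mask, roi)

  small <- sub
  d <- dim(sub$data)
  if (!is.null(downsample_to) && (d[2] > downsample_to || d[3] > downsample_to))
    small <- downsample_xy(sub, downsample_to)

  empty <- sum(small$data) == 0L
  if (empty) {
    len <- list(length_voxels = 0L, length_um = 0)
    bp <- list(branch_points = 0L, junction_voxels = 0L)
    radius_vox <- NA_real_; radius_um <- NA_real_
    sholl <- NULL
  } else {
    edm <- euclidean_distance_map(small)
    if (is.null(prune_spurs_below)) {
      fg_edm <- edm$data[small$data == 1L]
      prune_spurs_below <- 2 * stats::quantile(fg_edm, 0.99) + 2
    }
    skel <- skeletonize_3d(small, prune_spurs_below = prune_spurs_below)
    len <- network_length(skel)
    bp <- count_branch_points(skel, edm = edm)
    rad <- mean_vessel_radius(edm, skel)
    radius_vox <- rad$mean_radius
    edm_um <- euclidean_distance_map(small, physical = TRUE)
    radius_um <- mean_vessel_radius(edm_um, skel)$mean_radius
    mip <- max_intensity_projection(skel)
    if (is.null(sholl_center)) {
      fgpix <- which(mip > 0, arr.ind = TRUE)
      sholl_center <- c(mean(fgpix[, 1]) - 1, mean(fgpix[, 2]) - 1)
    }
    sholl <- sholl_profile(mip, sholl_center, sholl_max_radius, sholl_step)
  }

  dice <- NA_real_
  if (!is.null(template_mask))
    dice <- binary_overlap_metrics(crop_to_roi(mask, roi),
                                   crop_to_roi(template_mask, roi))$dice

  rec <- data.frame(sample_id = sample_id,
                    volume_um3 = vol,
                    surface_voxels = surf$count,
                    surface_um3 = surf$surface_um3,
                    density = dens,
                    length_voxels = len$length_voxels,
                    length_um = len$length_um,
                    branch_points = bp$branch_points,
                    junction_voxels = bp$junction_voxels,
                    mean_radius_voxels = radius_vox,
                    mean_radius_um = radius_um,
                    sholl_sum = if (is.null(sholl)) 0L else sholl$sum,
                    sholl_max = if (is.null(sholl)) 0L
                                else max(sholl$intersections),
                    dice_to_template = dice,
                    stringsAsFactors = FALSE)
  class(rec) <- c("metrics_record", "data.frame")
  attr(rec, "sholl") <- sholl
  attr(rec, "empty") <- empty
  rec
}

#' Write metrics records to CSV (one row per sample)
#' @param records a `metrics_record` or data.frame of row-bound records.
#' @param path output CSV path.
#' @export
write_metrics <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
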