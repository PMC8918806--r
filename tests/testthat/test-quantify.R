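# The eight-parameter morphometry stack.

test_that("vascular volume is count times voxel volume", {
  m <- array(0L, c(6, 10, 10))
  m[2:3, 2:6, 3:7] <- 1L  # 2*5*5 = 50 voxels
  bm <- binary_mask(m, c(0.33, 0.33, 0.5))
  expect_equal(vascular_volume(bm), 50 * 0.33 * 0.33 * 0.5)
  expect_equal(vascular_volume(binary_mask(array(0L, c(4, 4, 4)),
                                           c(0.33, 0.33, 0.5))), 0)
  # 100 voxels at the acquisition spacing
  m2 <- array(0L, c(5, 10, 10)); m2[1, 1:10, 1:10] <- 1L
  expect_equal(vascular_volume(binary_mask(m2, c(0.33, 0.33, 0.5))),
               100 * 0.05445, tolerance = 1e-12)
  # mask filling the roi gives exactly the roi volume
  roi <- roi_box(c(0, 0, 0), c(2, 4, 4))
  full <- binary_mask(array(1L, c(4, 8, 8)), c(1, 1, 1))
  expect_equal(vascular_volume(full, roi), prod(c(2, 4, 4)))
})

test_that("surface voxels follow the exposed-face definition", {
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  expect_equal(surface_voxels(binary_mask(one, c(1, 1, 1)))$count, 1)
  cube3 <- array(0L, c(7, 7, 7)); cube3[3:5, 3:5, 3:5] <- 1L
  expect_equal(surface_voxels(binary_mask(cube3, c(1, 1, 1)))$count, 26)
  cube5 <- array(0L, c(9, 9, 9)); cube5[3:7, 3:7, 3:7] <- 1L
  expect_equal(surface_voxels(binary_mask(cube5, c(1, 1, 1)))$count, 98)
  # voxels at the image border count the outside as background
  flat <- binary_mask(array(1L, c(1, 4, 4)), c(1, 1, 1))
  expect_equal(surface_voxels(flat)$count, 16)
})

test_that("vascular density is the foreground fraction of the ROI", {
  m <- array(0L, c(10, 10, 10))
  m[1:5, , ] <- 1L
  bm <- binary_mask(m, c(0.33, 0.33, 0.5))
  expect_equal(vascular_density(bm), 0.5)
  m2 <- array(0L, c(10, 10, 10)); m2[which(m2 == 0)[1:100]] <- 1L
  expect_equal(vascular_density(binary_mask(m2, c(1, 1, 1))), 0.1)
  expect_equal(vascular_density(binary_mask(array(0L, c(4, 4, 4)),
                                            c(1, 1, 1))), 0)
})

test_that("EDM equals the brute-force minimum over background voxels", {
  set.seed(19)
  for (rep in 1:8) {
    d <- sample(4:12, 3, replace = TRUE)
    m <- random_mask(d, runif(1, 0.3, 0.8))
    got <- euclidean_distance_map(binary_mask(m, c(1, 1, 1)))$data
    expect_equal(got, brute_edm(m), tolerance = 1e-12)
  }
  # solid 7-cube in background: centre is 4 from the nearest background
  cube <- array(0L, c(11, 11, 11)); cube[3:9, 3:9, 3:9] <- 1L
  edm <- euclidean_distance_map(binary_mask(cube, c(1, 1, 1)))$data
  expect_equal(edm[6, 6, 6], 4)
  expect_error(euclidean_distance_map(binary_mask(array(1L, c(3, 3, 3)),
                                                  c(1, 1, 1))),
               "background")
})

test_that("skeletonization preserves components and yields thin paths", {
  one <- array(0L, c(5, 5, 5)); one[3, 3, 3] <- 1L
  sk <- skeletonize_3d(binary_mask(one, c(1, 1, 1)))
  expect_identical(sk$data, one)

  tp <- generate_tube_phantom(phantom_spec(shape = c(15, 46, 15), radius = 3,
                                           spacing = c(1, 1, 1)))
  sk <- skeletonize_3d(tp$mask, prune_spurs_below = 8)
  nc <- vasquant:::neighbor_count26_cpp(sk$data)
  expect_equal(max(vasquant:::label3d_cpp(sk$data, 26L)), 1)  # one path
  expect_lte(max(nc[sk$data == 1L]), 2)                       # no junctions

  set.seed(23)
  for (rep in 1:5) {
    m <- random_mask(c(10, 12, 12), 0.35)
    before <- max(vasquant:::label3d_cpp(m, 26L))
    sk <- skeletonize_3d(binary_mask(m, c(1, 1, 1)))
    after <- max(vasquant:::label3d_cpp(sk$data, 26L))
    expect_equal(after, before)
  }
})

test_that("network length counts voxels and calibrates step lengths", {
  e <- binary_mask(array(0L, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(network_length(e)$length_voxels, 0)
  line <- array(0L, c(3, 60, 3)); line[2, 6:55, 2] <- 1L
  len <- network_length(binary_mask(line, c(0.5, 0.5, 0.5)))
  expect_equal(len$length_voxels, 50)
  expect_equal(len$length_steps, 49)
  expect_equal(len$length_um, 49 * 0.5)
  # tube phantom: within the end-erosion tolerance of the true length
  tp <- generate_tube_phantom(phantom_spec(shape = c(15, 50, 15), radius = 3,
                                           spacing = c(1, 1, 1)),
                              control_points = rbind(c(7, 5, 7), c(7, 45, 7)))
  sk <- skeletonize_3d(tp$mask, prune_spurs_below = 8)
  expect_gte(network_length(sk)$length_voxels, 37)
  expect_lte(network_length(sk)$length_voxels, 43)
})

test_that("branch points: none on paths, one per junction, clusters merged", {
  line <- array(0L, c(3, 30, 3)); line[2, 3:28, 2] <- 1L
  expect_equal(count_branch_points(binary_mask(line, c(1, 1, 1)))$branch_points,
               0)
  # perfect Y meeting at one voxel
  y <- array(0L, c(3, 21, 21))
  y[2, 1:10, 11] <- 1L
  for (k in 1:8) { y[2, 10 + k, 11 + k] <- 1L; y[2, 10 + k, 11 - k] <- 1L }
  bp <- count_branch_points(binary_mask(y, c(1, 1, 1)))
  expect_equal(bp$branch_points, 1)
})

test_that("tree phantoms recover their construction branch count exactly", {
  for (k in c(3, 5)) {
    sp <- phantom_spec(shape = c(96, 192, 192), n_bifurcations = k,
                       seed = 100 + k, spacing = c(1, 1, 1),
                       radius_range = c(2.5, 4),
                       segment_length_range = c(30, 45))
    tr <- generate_tree_phantom(sp)
    edm <- euclidean_distance_map(tr$mask)
    sk <- skeletonize_3d(tr$mask, prune_spurs_below = 10)
    bp <- count_branch_points(sk, edm = edm)
    expect_equal(bp$branch_points, k)
    len <- network_length(sk)
    expect_lt(abs(len$length_steps / tr$truth$length_voxels - 1), 0.075)
  }
})

test_that("radius estimation recovers digital tube radii within half a voxel", {
  for (r in c(2, 3, 4, 6)) {
    d <- c(2 * r + 9, 80, 2 * r + 9)
    sp <- phantom_spec(shape = d, radius = r, spacing = c(1, 1, 1))
    tp <- generate_tube_phantom(sp)
    edm <- euclidean_distance_map(tp$mask)
    sk <- skeletonize_3d(tp$mask, prune_spurs_below = 2 * r + 2)
    est <- mean_vessel_radius(edm, sk)
    expect_lte(abs(est$mean_radius - r), 0.5)
  }
  # thicker tube reads larger; pooled mean sits between
  mk <- function(r, d3) generate_tube_phantom(
    phantom_spec(shape = c(17, 60, d3), radius = r, spacing = c(1, 1, 1)),
    control_points = rbind(c(8, 6, d3 %/% 2), c(8, 54, d3 %/% 2)))
  t2 <- mk(2, 15); t4 <- mk(4, 17)
  pooled <- array(0L, c(17, 60, 32))
  pooled[, , 1:15] <- t2$mask$data
  pooled[, , 16:32] <- t4$mask$data
  pm <- binary_mask(pooled, c(1, 1, 1))
  edm <- euclidean_distance_map(pm)
  sk <- skeletonize_3d(pm, prune_spurs_below = 8)
  lab <- vasquant:::label3d_cpp(sk$data, 26L)
  r_each <- vapply(1:2, function(i) {
    sel <- (lab == i) * 1L; dim(sel) <- dim(pooled)
    mean_vessel_radius(edm, binary_mask(sel, c(1, 1, 1)))$mean_radius
  }, numeric(1))
  expect_gt(max(r_each), min(r_each))
  pooled_r <- mean_vessel_radius(edm, sk)$mean_radius
  expect_lte(abs(pooled_r - 3), 0.6)
  expect_error(mean_vessel_radius(edm, binary_mask(array(0L, dim(pooled)),
                                                   c(1, 1, 1))), "empty")
})

test_that("Sholl profiles count angular runs with the workflow defaults", {
  img <- matrix(0L, 64, 64)
  p0 <- sholl_profile(img, c(32, 32), max_radius = 20, step = 5)
  expect_true(all(p0$intersections == 0))
  expect_equal(p0$radii, c(5, 10, 15, 20))

  # single straight ray: one crossing at every shell it spans
  ray <- matrix(0L, 64, 64)
  ray[32, 32:60] <- 1L
  pr <- sholl_profile(ray, c(31, 31), max_radius = 25, step = 5)
  expect_true(all(pr$intersections == 1))

  # Y bifurcating at radius 10: one crossing at r=5, two at r=15
  yt <- matrix(0L, 101, 101)
  yt[51, 51:61] <- 1L
  for (k in 1:30) {
    yt[51 - round(k * 0.45), 61 + k] <- 1L
    yt[51 + round(k * 0.45), 61 + k] <- 1L
  }
  py <- sholl_profile(yt, c(50, 50), max_radius = 15, step = 5)
  expect_equal(py$intersections[1], 1)
  expect_equal(py$intersections[3], 2)

  expect_equal(formals(sholl_profile)$max_radius, 700)
  expect_equal(formals(sholl_profile)$step, 5)
  expect_error(sholl_profile(img, c(70, 32)), "outside")
})

test_that("volume, surface and density are translation invariant; length and branch counts survive 90-degree rotation", {
  base <- array(0L, c(20, 48, 48))
  base[6:10, 4:44, 22:26] <- 1L   # long bar along y, odd cross-section
  base[6:10, 22:26, 22:46] <- 1L  # side branch along x
  m1 <- binary_mask(base, c(1, 1, 1))
  shifted <- array(0L, dim(base))
  shifted[7:11, 5:45, 23:27] <- base[6:10, 4:44, 22:26]
  shifted[7:11, 23:27, 23:47] <- base[6:10, 22:26, 22:46]
  m2 <- binary_mask(shifted, c(1, 1, 1))
  expect_equal(vascular_volume(m2), vascular_volume(m1))
  expect_equal(surface_voxels(m2)$count, surface_voxels(m1)$count)
  expect_equal(vascular_density(m2), vascular_density(m1))

  # 90-degree in-plane rotation (axis transpose): the branch count is
  # exactly invariant; the voxel-count length can differ by a few voxels
  # because thinning deletes sequentially
  rot <- binary_mask(aperm(base, c(1, 3, 2)), c(1, 1, 1))
  sk1 <- skeletonize_3d(m1, prune_spurs_below = 6)
  skr <- skeletonize_3d(rot, prune_spurs_below = 6)
  expect_equal(count_branch_points(skr)$branch_points,
               count_branch_points(sk1)$branch_points)
  expect_equal(count_branch_points(sk1)$branch_points, 1)
  expect_lt(abs(network_length(skr)$length_voxels /
                  network_length(sk1)$length_voxels - 1), 0.05)
})

test_that("quantify_region composes the stack and is deterministic", {
  sp <- phantom_spec(shape = c(48, 110, 110), n_bifurcations = 3, seed = 51,
                     spacing = c(1, 1, 1), radius_range = c(2.5, 4),
                     segment_length_range = c(25, 40))
  tr <- generate_tree_phantom(sp)
  rec <- quantify_region(tr$mask, sample_id = "tree", downsample_to = NULL)
  expect_equal(rec$volume_um3, tr$truth$volume_um3)
  expect_equal(rec$branch_points, tr$truth$branch_count)
  expect_equal(rec$density, sum(tr$mask$data) / prod(dim(tr$mask$data)))
  expect_true(rec$mean_radius_voxels > 1.5 &&
                rec$mean_radius_voxels < 5)
  # identity registration does not change the record
  reg <- apply_rigid(tr$mask, rigid_transform())
  rec2 <- quantify_region(reg, sample_id = "tree", downsample_to = NULL)
  expect_equal(rec2[, -1], rec[, -1])

  empty <- binary_mask(array(0L, c(10, 12, 12)), c(1, 1, 1))
  rec0 <- quantify_region(empty)
  expect_equal(rec0$volume_um3, 0)
  expect_equal(rec0$branch_points, 0)
  expect_true(is.na(rec0$mean_radius_voxels))
  expect_true(attr(rec0, "empty"))
})

test_that("quantify_region downsamples wide masks before the skeleton stages", {
  m <- array(0L, c(4, 1040, 1040))
  m[2:3, 200:840, 515:525] <- 1L
  bm <- binary_mask(m, c(0.33, 0.33, 0.5))
  rec <- quantify_region(bm, downsample_to = 512L, sample_id = "wide")
  # volume computed at full resolution
  expect_equal(rec$volume_um3, sum(m) * 0.33 * 0.33 * 0.5)
  expect_gt(rec$length_voxels, 200)  # skeleton from the 512-wide grid
  expect_lt(rec$length_voxels, 400)
})
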