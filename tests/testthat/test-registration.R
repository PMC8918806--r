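# Landmark and automatic rigid registration, resampling, population maps.
# The automatic-registration displacement-recovery check at full phantom
# scale lives in test-acceptance.R; here a reduced-size variant keeps the
# unit suite fast.

make_landmarks <- function(n = 11, seed = 1) {
  set.seed(seed)
  landmark_set(sprintf("lm%02d", 1:n),
               runif(n, 0, 200), runif(n, 0, 600), runif(n, 0, 120))
}

test_that("landmark fit is exact on identical and rigidly moved sets", {
  lm <- make_landmarks()
  fit0 <- fit_landmark_rigid(lm, lm)
  expect_lt(max(abs(fit0$transform$R - diag(3))), 1e-12)
  expect_lt(max(abs(fit0$transform$t)), 1e-12)
  expect_lt(fit0$rms_residual, 1e-12)

  xf <- rigid_transform(vasquant:::euler_to_rotmat(30, 0, 0),
                        t = c(5, -3, 2), center = c(0, 0, 0))
  moved <- transform_landmarks(lm, xf)
  fit <- fit_landmark_rigid(lm, moved)
  expect_lt(max(abs(fit$transform$R - xf$R)), 1e-9)
  expect_lt(fit$rms_residual, 1e-9)
  # action on the points matches regardless of centre parameterisation
  refit <- transform_landmarks(lm, fit$transform)
  expect_lt(max(abs(landmark_matrix(refit) - landmark_matrix(moved))), 1e-9)
})

test_that("landmark fit rejects degenerate configurations", {
  short <- landmark_set(c("a", "b"), c(0, 1), c(0, 0), c(0, 0))
  expect_error(fit_landmark_rigid(short, short), "3 landmarks")
  line <- landmark_set(c("a", "b", "c", "d"), c(0, 1, 2, 3),
                       c(0, 2, 4, 6), c(0, 1, 2, 3))
  expect_error(fit_landmark_rigid(line, line), "collinear")
  lm <- make_landmarks(5)
  lm2 <- lm; lm2$name <- rev(lm2$name)
  expect_error(fit_landmark_rigid(lm, lm2), "names")
})

test_that("landmark-noise residuals follow the rigid-fit expectation", {
  # with isotropic landmark noise sd sigma on the target points, the
  # expected RMS residual of an n-point rigid fit is sigma*sqrt(2(n-3)/n)
  # (6 of the 3n error dof are absorbed by the fitted transform);
  # Monte-Carlo mean must sit within 20% of the closed form
  lm <- make_landmarks(11, seed = 2)
  sigma <- 1
  set.seed(77)
  rms <- replicate(500, {
    noisy <- lm
    noisy$x_um <- noisy$x_um + rnorm(11, 0, sigma)
    noisy$y_um <- noisy$y_um + rnorm(11, 0, sigma)
    noisy$z_um <- noisy$z_um + rnorm(11, 0, sigma)
    fit_landmark_rigid(lm, noisy)$rms_residual
  })
  expected <- sigma * sqrt((3 * 11 - 6) / 11)
  expect_lt(abs(mean(rms) / expected - 1), 0.2)
})

test_that("fit is invariant under a common rigid motion of both sets", {
  lm_m <- make_landmarks(8, seed = 3)
  lm_t <- make_landmarks(8, seed = 4)
  fit1 <- fit_landmark_rigid(lm_m, lm_t)
  common <- rigid_transform(vasquant:::euler_to_rotmat(40, 15, -25),
                            t = c(12, 5, -8), center = c(50, 50, 50))
  fit2 <- fit_landmark_rigid(transform_landmarks(lm_m, common),
                             transform_landmarks(lm_t, common))
  expect_equal(fit2$rms_residual, fit1$rms_residual, tolerance = 1e-9)
})

test_that("apply_rigid: identity, exact integer shifts, and composition", {
  set.seed(21)
  m <- binary_mask(random_mask(c(8, 10, 12), 0.3), c(1, 1, 1))
  ident <- rigid_transform()
  expect_identical(apply_rigid(m, ident)$data, m$data)

  # pure integer translation with nearest interpolation = index shift
  xf <- rigid_transform(t = c(2, -1, 3))  # (x, y, z) um = voxels here
  shifted <- apply_rigid(m, xf)
  oracle <- array(0L, dim(m$data))
  oracle[(1 + 3):8, 1:(10 - 1), (1 + 2):12] <-
    m$data[1:(8 - 3), 2:10, 1:(12 - 2)]
  expect_identical(shifted$data, oracle)

  # composition on a smooth grid within linear-interpolation tolerance
  g <- voxel_grid(array(rnorm(16 * 16 * 16), c(16, 16, 16)), c(1, 1, 1))
  g <- voxel_grid(vasquant:::conv_sep3d_cpp(
    g$data, rep(1 / 5, 5), rep(1 / 5, 5), rep(1 / 5, 5)), c(1, 1, 1))
  xf1 <- rigid_transform(vasquant:::euler_to_rotmat(8, 0, 0), c(1, 0.5, 0),
                         center = c(7.5, 7.5, 7.5))
  xf2 <- rigid_transform(vasquant:::euler_to_rotmat(0, 5, 0), c(-0.5, 1, 0),
                         center = c(7.5, 7.5, 7.5))
  two_step <- apply_rigid(apply_rigid(g, xf1), xf2)
  one_step <- apply_rigid(g, compose_rigid(xf2, xf1))
  core <- function(a) a[5:12, 5:12, 5:12]
  expect_lt(mean(abs(core(two_step$data) - core(one_step$data))),
            0.05 * stats::sd(g$data))
  expect_error(apply_rigid(g, xf1, "cubic"))
})

test_that("self-registration returns the identity with full overlap", {
  sp <- phantom_spec(shape = c(48, 96, 96), n_bifurcations = 3, seed = 5,
                     spacing = c(1, 1, 1), radius_range = c(2.5, 4),
                     segment_length_range = c(18, 28))
  tr <- generate_tree_phantom(sp)
  res <- register_automatic_rigid(tr$mask, tr$mask,
                                  auto_reg_params(downsample_factors = c(4, 2),
                                                  angular_range = 60))
  ang <- vasquant:::rotmat_to_euler(res$transform$R)
  expect_lt(max(abs(ang)), 0.5)
  expect_lt(max(abs(res$transform$t)), 0.5)
  reg <- apply_rigid(tr$mask, res$transform, target = tr$mask)
  expect_gte(binary_overlap_metrics(reg, tr$mask)$dice, 0.99)
  expect_false(res$low_confidence)
})

test_that("registration of dissimilar structures is flagged low-confidence", {
  set.seed(10)
  a <- array(0L, c(24, 48, 48)); a[8:16, 6:20, 6:20] <- 1L
  b <- array(0L, c(24, 48, 48)); b[4:6, 36:46, 30:46] <- 1L
  res <- register_automatic_rigid(
    binary_mask(a, c(1, 1, 1)), binary_mask(b, c(1, 1, 1)),
    auto_reg_params(downsample_factors = c(4, 2), angular_range = 30,
                    max_shift = 5))
  expect_true(res$low_confidence)
  expect_error(register_automatic_rigid(
    binary_mask(array(0L, c(8, 8, 8)), c(1, 1, 1)),
    binary_mask(b, c(1, 1, 1))), "empty")
})

test_that("population average maps count voxel-wise overlap exactly", {
  set.seed(12)
  m1 <- binary_mask(random_mask(c(6, 8, 8), 0.4), c(1, 1, 1))
  pam6 <- build_population_average_map(rep(list(m1), 6), "t0")
  expect_identical(pam6$mean_map, m1$data * 1.0)
  expect_equal(pam6$n_samples, 6)

  m2 <- m1
  half <- which(m2$data == 1L)
  half <- half[seq_len(floor(length(half) / 2))]
  m2$data[half] <- 0L
  pam <- build_population_average_map(list(m1, m2))
  expect_true(all(pam$mean_map %in% c(0, 0.5, 1)))
  counts <- pam$mean_map * 2
  expect_equal(counts, m1$data + m2$data)
  # conservation: mean of the map = mean foreground fraction of inputs
  expect_equal(mean(pam$mean_map),
               mean(c(mean(m1$data), mean(m2$data))))
  expect_error(build_population_average_map(list()), "at least one")
  expect_error(build_population_average_map(list(
    m1, binary_mask(array(0L, c(2, 2, 2)), c(1, 1, 1)))), "shape")
})
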