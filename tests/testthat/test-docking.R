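# FFT translation search validated against a direct-space oracle, plus
# seeded pose- and multi-copy recovery on phantoms. Docking itself is
# fully deterministic; seeds only generate the test instances.

test_that("FFT cross-correlation equals the direct-space computation", {
  set.seed(10)
  n <- 32
  a <- array(stats::rnorm(n^3), c(n, n, n))
  b <- array(stats::rnorm(n^3), c(n, n, n))
  cc <- cross_correlate_translations(voxel_grid(a, 2), voxel_grid(b, 2))
  shifts <- cbind(sample(0:(n - 1), 5), sample(0:(n - 1), 5),
                  sample(0:(n - 1), 5))
  for (i in 1:5) {
    s <- shifts[i, ]
    expect_lt(abs(cc[s[1] + 1, s[2] + 1, s[3] + 1] -
                    direct_ncc_at_shift(a, b, s)), 1e-6)
  }
})

test_that("correlation peaks behave: self, known shift, noise null", {
  sub <- cyclomap:::subunit_blob_model(44, 70)
  dens <- model_to_density(sub, 1.8, 14, 64)
  cc <- cross_correlate_translations(dens, dens)
  pk <- cyclomap:::wrapped_peak(cc)
  expect_equal(pk$score, 1, tolerance = 1e-9)
  expect_equal(pk$shift, c(0, 0, 0))
  # probe against itself shifted by (9.0, -5.4, 3.6) A = (5, -3, 2) voxels
  shifted <- apply_pose(sub, rigid_pose(0, 0, 0, c(9.0, -5.4, 3.6)))
  map <- model_to_density(shifted, 1.8, 14, 64)
  pk2 <- cyclomap:::wrapped_peak(cross_correlate_translations(map, dens))
  expect_lt(max(abs(pk2$shift * 1.8 - c(9.0, -5.4, 3.6))), 0.9)
  # pure-noise map: no spurious high peak
  set.seed(11)
  noise <- voxel_grid(array(stats::rnorm(64^3), c(64, 64, 64)), 1.8)
  ccn <- cross_correlate_translations(noise, dens)
  expect_lt(max(abs(ccn)), 0.2)
})

test_that("NCC is invariant to affine intensity changes of either input", {
  set.seed(12)
  n <- 24
  a <- voxel_grid(array(stats::rnorm(n^3), c(n, n, n)), 2)
  b <- voxel_grid(array(stats::rnorm(n^3), c(n, n, n)), 2)
  cc0 <- cross_correlate_translations(a, b)
  a2 <- voxel_grid(3.7 * a$data + 11, 2)
  b2 <- voxel_grid(0.2 * b$data - 5, 2)
  expect_lt(max(abs(cross_correlate_translations(a2, b) - cc0)), 1e-9)
  expect_lt(max(abs(cross_correlate_translations(a, b2) - cc0)), 1e-9)
})

test_that("rigid poses compose, invert and canonicalize", {
  p <- rigid_pose(400, 30, -20, c(1, 2, 3))
  expect_equal(p$alpha, 40)
  expect_equal(p$gamma, 340)
  # applying a pose then its inverse rotation returns the model
  sub <- cyclomap:::subunit_blob_model()
  posed <- apply_pose(sub, rigid_pose(25, 70, 110, c(4, -2, 6)))
  R <- cyclomap:::euler_zyz_matrix(25, 70, 110)
  back <- posed
  xyz <- sweep(cyclomap:::model_coords(posed), 2, c(4, -2, 6))
  xyz <- xyz %*% R  # multiply by R^-1 transposed = R
  back$x <- xyz[, 1]; back$y <- xyz[, 2]; back$z <- xyz[, 3]
  expect_equal(cyclomap:::model_coords(back), cyclomap:::model_coords(sub),
               tolerance = 1e-9)
})

test_that("rigid_fit recovers a seeded ground-truth pose", {
  sub <- cyclomap:::subunit_blob_model()
  truth <- rigid_pose(132, 67, 288, c(5, -7, 3.2))
  map <- model_to_density(apply_pose(sub, truth), 2.5, 18, 48)
  fits <- rigid_fit(map, sub, angular_step = 30, resolution = 18, n_best = 1)
  f <- fits[[1]]
  expect_gt(f$score, 0.99)
  expect_lt(rotation_angle_between(cyclomap:::pose_matrix(truth),
                                   cyclomap:::pose_matrix(f$pose)), 15)
  expect_lt(max(abs(f$pose$translation - truth$translation)), 2.5)
  # identity case
  map0 <- model_to_density(sub, 2.5, 18, 48)
  f0 <- rigid_fit(map0, sub, angular_step = 30, resolution = 18,
                  n_best = 1)[[1]]
  expect_gt(f0$score, 0.999)
  expect_lt(rotation_angle_between(diag(3),
                                   cyclomap:::pose_matrix(f0$pose)), 5)
  expect_error(rigid_fit(voxel_grid(array(0, c(16, 16, 16)), 2), sub,
                         angular_step = 30), "zero variance")
})

test_that("sequential_multifit recovers all six phantom subunits", {
  p <- make_hexamer_phantom(small_hexamer_spec())
  mf <- sequential_multifit(p$grid, p$subunit, n_copies = 6,
                            angular_step = 40, resolution = 16)
  expect_length(mf, 6)
  truthR <- lapply(p$poses, cyclomap:::pose_matrix)
  used <- integer(0)
  ang_errs <- numeric(6)
  for (j in seq_along(mf)) {
    f <- mf[[j]]
    errs <- vapply(seq_along(truthR), function(i) {
      rotation_angle_between(truthR[[i]], cyclomap:::pose_matrix(f$pose)) +
        sqrt(sum((p$poses[[i]]$translation - f$pose$translation)^2))
    }, 0)
    best <- which.min(errs)
    used <- c(used, best)
    ang_errs[j] <- rotation_angle_between(truthR[[best]],
                                          cyclomap:::pose_matrix(f$pose))
    expect_lt(sqrt(sum((p$poses[[best]]$translation -
                          f$pose$translation)^2)), 2.5)
    expect_equal(f$clash_count, 0L)
  }
  expect_setequal(used, 1:6)        # each subunit found exactly once
  expect_lt(mean(ang_errs), 40)     # mean angular error below the step
})

test_that("single-copy multifit equals the top rigid_fit hit", {
  sub <- cyclomap:::subunit_blob_model()
  map <- model_to_density(apply_pose(sub, rigid_pose(60, 30, 10, c(2, 1, -3))),
                          2.5, 18, 48)
  one <- sequential_multifit(map, sub, n_copies = 1, angular_step = 30,
                             resolution = 18)
  top <- rigid_fit(map, sub, angular_step = 30, resolution = 18,
                   n_best = 1)[[1]]
  expect_equal(one[[1]]$pose, top$pose)
  expect_equal(one[[1]]$score, top$score)
})

test_that("clash_count matches direct distance counting", {
  m <- cyclomap:::subunit_blob_model()
  # model against itself: every atom clashes with its own copy
  expect_gte(clash_count(m, m), nrow(m))
  far <- apply_pose(m, rigid_pose(0, 0, 0, c(50, 0, 0)))
  expect_identical(clash_count(m, far), 0L)
  # analytic two-atom case
  a <- atomic_model("C", 0, 0, 0)
  b <- atomic_model("C", 1.9, 0, 0)
  expect_identical(clash_count(a, b, cutoff = 2.0), 1L)
  expect_identical(clash_count(a, b, cutoff = 1.8), 0L)
  # oracle on random point sets
  set.seed(13)
  pa <- atomic_model(rep("C", 60), stats::runif(60, -9, 9),
                     stats::runif(60, -9, 9), stats::runif(60, -9, 9))
  pb <- atomic_model(rep("C", 60), stats::runif(60, -9, 9),
                     stats::runif(60, -9, 9), stats::runif(60, -9, 9))
  d <- as.matrix(stats::dist(rbind(cyclomap:::model_coords(pa),
                                   cyclomap:::model_coords(pb))))
  direct <- sum(d[1:60, 61:120] < 2.0)
  expect_identical(clash_count(pa, pb, 2.0), as.integer(direct))
})
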