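# Surface extraction, geometric point-to-ellipsoid distance, least-squares
# fitting and voxel ROI rasterization.

test_that("mask surface extraction matches counting oracles", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  expect_equal(mask_surface_points(m), matrix(c(5, 5, 5), 1),
               ignore_attr = TRUE)

  cube <- array(FALSE, c(9, 9, 9)); cube[3:7, 3:7, 3:7] <- TRUE
  expect_identical(nrow(mask_surface_points(cube)), 98L)  # 5^3 - 3^3

  # digital ball of radius 8: every surface voxel near the continuous sphere
  d <- c(21, 21, 21); ctr <- c(11, 11, 11)
  idx <- arrayInd(seq_len(prod(d)), d)
  ball <- array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= 8, d)
  pts <- mask_surface_points(ball)
  r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  expect_true(all(abs(r - 8) <= 1.5))
  expect_error(mask_surface_points(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("point-to-ellipsoid distance matches closed forms", {
  sph <- ellipsoid(c(0, 0, 0), c(1, 1, 1))
  expect_equal(point_ellipsoid_distance(c(3, 0, 0), sph), 2)
  expect_equal(point_ellipsoid_distance(c(0, 0, 0), sph), 1)

  e <- ellipsoid(c(0, 0, 0), c(4, 2, 1))
  expect_equal(point_ellipsoid_distance(c(6, 0, 0), e), 2)
  expect_equal(point_ellipsoid_distance(c(0, 0, 0), e), 1)  # smallest axis
  expect_lt(point_ellipsoid_distance(c(0, 2, 0), e), 1e-8)  # on surface

  # translated + rotated frame
  set.seed(7)
  R <- random_rotation(35)
  ctr <- c(5, -2, 1)
  e2 <- ellipsoid(ctr, c(4, 2, 1), R)
  p_local <- c(6, 0, 0)
  p_world <- as.numeric(p_local %*% R) + ctr   # rows of R = directions
  expect_equal(point_ellipsoid_distance(p_world, e2), 2, tolerance = 1e-6)
})

test_that("distance agrees with an independent surface-minimization oracle", {
  set.seed(8)
  for (i in 1:12) {
    axes <- sort(runif(3, 0.5, 5), decreasing = TRUE)
    p <- rnorm(3, sd = 3)
    d_mine <- point_ellipsoid_distance(p, ellipsoid(c(0, 0, 0), axes))
    d_oracle <- oracle_ellipsoid_distance(p, axes)
    expect_equal(d_mine, d_oracle, tolerance = 1e-3)
  }
})

test_that("fitting exact surface samples recovers the generating ellipsoid", {
  set.seed(9)
  axes <- c(10, 6, 4); ctr <- c(32, 30, 28)
  R <- random_rotation(25)
  fit <- fit_ellipsoid(ellipsoid_surface_points(600, ctr, axes, R))
  e <- fit$ellipsoid
  expect_lt(max(abs(e$center - ctr)), 0.25)
  expect_lt(max(abs(e$semi_axes - axes)), 0.25)
  for (i in 1:3) {
    cosang <- abs(sum(e$orientation[i, ] * R[i, ]))
    expect_gt(cosang, cos(2 * pi / 180))
  }
  expect_lt(fit$report$final_energy, 1e-6)
  expect_true(fit$report$converged)
})

test_that("a unit sphere fits with all semi-axes 1", {
  set.seed(10)
  fit <- fit_ellipsoid(ellipsoid_surface_points(400, c(0, 0, 0), c(1, 1, 1)))
  expect_equal(fit$ellipsoid$semi_axes, c(1, 1, 1), tolerance = 1e-3)
  expect_lt(fit$report$final_energy, 1e-6)
})

test_that("voxelized masks fit within 0.6 voxel of the generating axes", {
  d <- c(40, 40, 40); ctr <- c(20.3, 19.6, 20.1); axes <- c(9, 5.5, 4)
  set.seed(11)
  R <- random_rotation(20)
  idx <- arrayInd(seq_len(prod(d)), d)
  q <- sweep(idx, 2, ctr) %*% t(R)
  solid <- array(rowSums(sweep(q, 2, axes, `/`)^2) <= 1, d)
  fit <- fit_ellipsoid(mask_surface_points(solid))
  expect_lt(max(abs(fit$ellipsoid$semi_axes - axes)), 0.6)
  expect_lt(max(abs(fit$ellipsoid$center - ctr)), 0.6)
})

test_that("the fit is equivariant under rigid motions of the points", {
  set.seed(12)
  pts <- ellipsoid_surface_points(500, c(0, 0, 0), c(7, 4, 2.5),
                                  random_rotation(15))
  base <- fit_ellipsoid(pts)$ellipsoid
  Rm <- random_rotation(40); tv <- c(3, -8, 5)
  moved <- pts %*% t(Rm) + rep(tv, each = nrow(pts))
  e2 <- fit_ellipsoid(moved)$ellipsoid
  expect_equal(e2$semi_axes, base$semi_axes, tolerance = 1e-3)
  expect_equal(e2$center, as.numeric(Rm %*% base$center) + tv,
               tolerance = 1e-3)
})

test_that("degenerate point sets are rejected", {
  flat <- cbind(matrix(runif(60), 30, 2), 0)
  expect_error(fit_ellipsoid(flat), "coplanar")
  expect_error(fit_ellipsoid(matrix(rnorm(12), 4, 3)), "at least 10")
})

test_that("ellipsoid ROI voxel counts match the continuous volume", {
  fine <- spect_volume(array(0, c(48, 48, 48)))
  sph <- ellipsoid(c(6, 6, 6), c(5.2, 5.2, 5.2))
  n <- sum(ellipsoid_roi(sph, fine, spacing = rep(0.25, 3))$data)
  expect_equal(n * 0.25^3, 4 / 3 * pi * 5.2^3, tolerance = 0.03)

  grid <- spect_volume(array(0, c(40, 40, 40)))

  unit <- ellipsoid(c(20, 20, 20), c(1, 1, 1) + 1e-9)
  m <- ellipsoid_roi(unit, grid)$data
  # brute-force check of the quadratic inequality voxel by voxel
  idx <- which(m, arr.ind = TRUE)
  expect_identical(nrow(idx), 7L)  # centre + 6 face neighbours
  expect_error(ellipsoid_roi(ellipsoid(c(99, 99, 99), c(1, 1, 1)), grid),
               "intersect")
})
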