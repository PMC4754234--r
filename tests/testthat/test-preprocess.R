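# Alpha-stable estimation, intensity normalization, rigid registration and
# template construction.

test_that("a Gaussian sample is recognised as the alpha = 2 stable law", {
  set.seed(42)
  m <- 10; s <- 2
  f <- fit_alpha_stable(rnorm(1e5, m, s))
  expect_equal(f$alpha, 2, tolerance = 0.1)
  expect_lt(abs(f$beta), 0.1)
  expect_equal(f$mu, m, tolerance = 0.1 * m)
  expect_equal(f$gamma, s / sqrt(2), tolerance = 0.1 * s / sqrt(2))
})

test_that("the stable fit is location and scale equivariant", {
  set.seed(43)
  x <- 5 + 2 * abs(rnorm(2e4))^1.2
  f0 <- fit_alpha_stable(x)
  fs <- fit_alpha_stable(x + 7)
  expect_equal(fs$mu, f0$mu + 7, tolerance = 0.05 * f0$gamma)
  expect_equal(fs$gamma, f0$gamma, tolerance = 1e-9)
  fk <- fit_alpha_stable(3 * x)
  expect_equal(fk$gamma, 3 * f0$gamma, tolerance = 1e-9)
})

test_that("sample-size and degeneracy preconditions are enforced", {
  expect_error(fit_alpha_stable(rnorm(100)), "at least")
  expect_error(fit_alpha_stable(rep(1, 1000)), "degenerate")
})

test_that("normalization maps every image to the pooled dispersion/location", {
  vols <- lapply(1:3, function(i) control_phantom(seed = i)$volume)
  res <- normalize_intensity(vols)
  gs <- res$model$gamma_star
  # re-fitting each normalized volume (over the voxels its own fit used)
  # recovers (gamma*, mu*)
  for (i in seq_along(vols)) {
    f <- fit_alpha_stable(res$volumes[[i]], mask = brain_mask(vols[[i]]))
    expect_equal(f$gamma, gs, tolerance = 0.05 * gs)
    expect_lt(abs(f$mu - res$model$mu_star), 0.05 * gs)
  }
  # fixed point of the linear map: renormalizing the output over the same
  # histogram sample is the identity
  res2 <- normalize_intensity(res$volumes, masks = lapply(vols, brain_mask))
  expect_true(all(abs(res2$model$per_image$a - 1) < 0.02))
  expect_true(all(abs(res2$model$per_image$b) < 0.02 * res2$model$gamma_star))
  # with masks re-derived from the normalized intensities, the residual is
  # bounded by the estimator tolerance
  res3 <- normalize_intensity(res$volumes)
  expect_true(all(abs(res3$model$per_image$a - 1) < 0.05))
  expect_true(all(abs(res3$model$per_image$b) < 0.05 * res3$model$gamma_star))
})

test_that("single or identical images normalize to themselves", {
  v <- control_phantom()$volume
  r1 <- normalize_intensity(list(v))
  expect_equal(r1$model$per_image$a, 1)
  expect_equal(r1$model$per_image$b, 0)
  expect_identical(r1$volumes[[1]]$data, v$data)

  r3 <- normalize_intensity(list(v, v, v))
  expect_equal(r3$model$per_image$a, rep(1, 3))
  expect_equal(r3$model$per_image$b, rep(0, 3))
})

test_that("an image and its rescaled copy normalize to the same volume", {
  v <- control_phantom()$volume
  v2 <- v; v2$data <- 2 * v$data; v2$id <- "double"
  res <- normalize_intensity(list(v, v2))
  expect_lt(max(abs(res$volumes[[1]]$data - res$volumes[[2]]$data)),
            0.05 * res$model$gamma_star)
})

test_that("registration of a volume to itself recovers the identity", {
  v <- control_phantom()$volume
  reg <- register_rigid(v, v)
  expect_lt(sqrt(sum(reg$transform$rotation^2)), 0.01)
  expect_lt(sqrt(sum(reg$transform$translation^2)), 0.5)
  expect_gt(reg$ncc, 0.999)
})

test_that("known rigid motions are recovered within tolerance", {
  v <- control_phantom()$volume
  shifted <- resample_rigid(v, v, rigid_transform(translation = c(6, -4, 2)))
  reg <- suppressWarnings(register_rigid(shifted, v))
  # registering back finds the inverse motion
  expect_lt(max(abs(reg$transform$translation + c(6, -4, 2))), 1)

  rot <- resample_rigid(v, v, rigid_transform(rotation = c(0, 0, 10 * pi / 180)))
  reg2 <- suppressWarnings(register_rigid(rot, v))
  expect_lt(abs(reg2$transform$rotation[3] + 10 * pi / 180), 2 * pi / 180)
  expect_error(register_rigid(spect_volume(array(1, c(8, 8, 8))), v), "constant")
})

test_that("the control template is exactly mid-plane symmetric", {
  tpl <- small_template()
  expect_identical(tpl$data, reflect_midplane(tpl)$data)
  ax <- striatr:::lr_axis(tpl)
  n <- dim(tpl$data)[ax]
  lo <- sum(tpl$data[seq_len(n / 2), , ])
  hi <- sum(tpl$data[seq(n / 2 + 1, n), , ])
  expect_identical(lo, hi)
  expect_error(build_template(list(control_phantom()$volume)), "at least 2")
})

test_that("averaging two identical symmetric phantoms reproduces them", {
  v <- control_phantom()$volume
  sym <- v
  sym$data <- (v$data + reflect_midplane(v)$data) / 2
  tpl <- build_template(list(sym, sym), iterations = 1)
  # identical inputs register to identity; only resampling noise remains
  expect_equal(tpl$data, sym$data, tolerance = 0.02)
})
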