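# McCulloch (1986) quantile-based estimation of alpha-stable parameters.
# The interpolation tables below are the published Tables III, IV, V and VII
# (psi_1, psi_2, psi_3, psi_5) of that method; standard constants.

.mcculloch <- local({
  nu_alpha_grid <- c(2.439, 2.5, 2.6, 2.7, 2.8, 3, 3.2, 3.5, 4, 5, 6, 8, 10, 15, 25)
  nu_beta_grid <- c(0, 0.1, 0.2, 0.3, 0.5, 0.7, 1)
  psi1 <- matrix(c(
    2.000, 2.000, 2.000, 2.000, 2.000, 2.000, 2.000,
    1.916, 1.924, 1.924, 1.924, 1.924, 1.924, 1.924,
    1.808, 1.813, 1.829, 1.829, 1.829, 1.829, 1.829,
    1.729, 1.730, 1.737, 1.745, 1.745, 1.745, 1.745,
    1.664, 1.663, 1.663, 1.668, 1.676, 1.676, 1.676,
    1.563, 1.560, 1.553, 1.548, 1.547, 1.547, 1.547,
    1.484, 1.480, 1.471, 1.460, 1.448, 1.438, 1.438,
    1.391, 1.386, 1.378, 1.364, 1.337, 1.318, 1.318,
    1.279, 1.273, 1.266, 1.250, 1.210, 1.184, 1.150,
    1.128, 1.121, 1.114, 1.101, 1.067, 1.027, 0.973,
    1.029, 1.021, 1.014, 1.004, 0.974, 0.935, 0.874,
    0.896, 0.892, 0.884, 0.883, 0.855, 0.823, 0.769,
    0.818, 0.812, 0.806, 0.801, 0.780, 0.756, 0.691,
    0.698, 0.695, 0.692, 0.689, 0.676, 0.656, 0.597,
    0.593, 0.590, 0.588, 0.586, 0.579, 0.563, 0.513), 15, 7, byrow = TRUE)
  psi2 <- matrix(c(
    0, 2.160, 1.000, 1.000, 1.000, 1.000, 1.000,
    0, 1.592, 3.390, 1.000, 1.000, 1.000, 1.000,
    0, 0.759, 1.800, 1.000, 1.000, 1.000, 1.000,
    0, 0.482, 1.048, 1.694, 1.000, 1.000, 1.000,
    0, 0.360, 0.760, 1.232, 2.229, 1.000, 1.000,
    0, 0.253, 0.518, 0.823, 1.575, 1.000, 1.000,
    0, 0.203, 0.410, 0.632, 1.244, 1.906, 1.000,
    0, 0.165, 0.332, 0.499, 0.943, 1.560, 1.000,
    0, 0.136, 0.271, 0.404, 0.689, 1.230, 2.195,
    0, 0.109, 0.216, 0.323, 0.539, 0.827, 1.917,
    0, 0.096, 0.190, 0.284, 0.472, 0.693, 1.759,
    0, 0.082, 0.163, 0.243, 0.412, 0.601, 1.596,
    0, 0.074, 0.147, 0.220, 0.377, 0.546, 1.482,
    0, 0.064, 0.128, 0.191, 0.330, 0.478, 1.362,
    0, 0.056, 0.112, 0.167, 0.285, 0.428, 1.274), 15, 7, byrow = TRUE)
  alpha_grid <- seq(2, 0.5, by = -0.1)
  beta_grid <- c(0, 0.25, 0.5, 0.75, 1)
  psi3 <- matrix(c(
    1.908, 1.908, 1.908, 1.908, 1.908,
    1.914, 1.915, 1.916, 1.918, 1.921,
    1.921, 1.922, 1.927, 1.936, 1.947,
    1.927, 1.930, 1.943, 1.961, 1.987,
    1.933, 1.940, 1.962, 1.997, 2.043,
    1.939, 1.952, 1.988, 2.045, 2.116,
    1.946, 1.967, 2.022, 2.106, 2.211,
    1.955, 1.984, 2.067, 2.188, 2.333,
    1.965, 2.007, 2.125, 2.294, 2.491,
    1.980, 2.040, 2.205, 2.435, 2.696,
    2.000, 2.085, 2.311, 2.624, 2.973,
    2.040, 2.149, 2.461, 2.886, 3.356,
    2.098, 2.244, 2.676, 3.265, 3.912,
    2.189, 2.392, 3.004, 3.844, 4.775,
    2.337, 2.634, 3.542, 4.808, 6.247,
    2.588, 3.073, 4.534, 6.636, 9.144), 16, 5, byrow = TRUE)
  psi5 <- matrix(c(
    0,  0.000,  0.000,  0.000,  0.000,
    0, -0.017, -0.032, -0.049, -0.064,
    0, -0.030, -0.061, -0.092, -0.123,
    0, -0.043, -0.088, -0.132, -0.179,
    0, -0.056, -0.111, -0.170, -0.232,
    0, -0.066, -0.134, -0.206, -0.283,
    0, -0.075, -0.154, -0.241, -0.335,
    0, -0.084, -0.173, -0.276, -0.390,
    0, -0.090, -0.192, -0.310, -0.447,
    0, -0.095, -0.208, -0.346, -0.508,
    0, -0.098, -0.223, -0.380, -0.576,
    0, -0.099, -0.237, -0.424, -0.652,
    0, -0.096, -0.250, -0.469, -0.742,
    0, -0.089, -0.262, -0.520, -0.853,
    0, -0.078, -0.272, -0.581, -0.997,
    0, -0.061, -0.279, -0.659, -1.198), 16, 5, byrow = TRUE)
  list(nu_alpha_grid = nu_alpha_grid, nu_beta_grid = nu_beta_grid,
       psi1 = psi1, psi2 = psi2,
       alpha_grid = alpha_grid, beta_grid = beta_grid,
       psi3 = psi3, psi5 = psi5)
})

# Bilinear interpolation in a table with grid clamping.
interp2 <- function(xg, yg, z, x, y) {
  x <- min(max(x, min(xg)), max(xg))
  y <- min(max(y, min(yg)), max(yg))
  ix <- findInterval(x, xg, rightmost.closed = TRUE)
  iy <- findInterval(y, yg, rightmost.closed = TRUE)
  ix <- min(max(ix, 1L), length(xg) - 1L)
  iy <- min(max(iy, 1L), length(yg) - 1L)
  tx <- (x - xg[ix]) / (xg[ix + 1] - xg[ix])
  ty <- (y - yg[iy]) / (yg[iy + 1] - yg[iy])
  (1 - tx) * (1 - ty) * z[ix, iy] + tx * (1 - ty) * z[ix + 1, iy] +
    (1 - tx) * ty * z[ix, iy + 1] + tx * ty * z[ix + 1, iy + 1]
}

#' Quantile-based alpha-stable parameter estimate
#'
#' McCulloch's consistent quantile estimator of the four parameters of a
#' (possibly skewed) alpha-stable law from a univariate sample: stability
#' exponent `alpha` in (0, 2\], skewness `beta` in \[-1, 1\], dispersion
#' `gamma` > 0 and location `mu`. When given a volume, the fit uses the
#' in-mask intensity sample (see [brain_mask()]).
#'
#' @param x Numeric sample, or a [spect_volume()].
#' @param mask Optional [spect_mask()] restricting the sample when `x` is a
#'   volume.
#' @param min_n Minimum sample size.
#' @return An object of class `alpha_stable_params`: list with `alpha`,
#'   `beta`, `gamma`, `mu` and the sample size `n`.
#' @export
fit_alpha_stable <- function(x, mask = NULL, min_n = 500) {
  if (inherits(x, "spect_volume")) {
    m <- if (is.null(mask)) brain_mask(x) else mask
    x <- x$data[m$data]
  }
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) < min_n)
    stop("alpha-stable fit needs at least ", min_n, " sample values, got ",
         length(x), call. = FALSE)
  q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7)
  if (q[5] - q[1] <= 0 || q[4] - q[2] <= 0)
    stop("degenerate (zero-variance) intensity sample", call. = FALSE)
  nu_a <- (q[5] - q[1]) / (q[4] - q[2])
  nu_b <- (q[5] + q[1] - 2 * q[3]) / (q[5] - q[1])
  tb <- .mcculloch
  if (nu_a >= 2.439) {
    alpha <- interp2(tb$nu_alpha_grid, tb$nu_beta_grid, tb$psi1, nu_a, abs(nu_b))
    alpha <- min(max(alpha, .Machine$double.eps), 2)
    beta <- interp2(tb$nu_alpha_grid, tb$nu_beta_grid, tb$psi2, nu_a, abs(nu_b))
    beta <- sign(nu_b) * min(max(beta, 0), 1)
  } else {
    alpha <- 2
    beta <- sign(nu_b)
  }
  ag <- rev(tb$alpha_grid); ord <- rev(seq_along(tb$alpha_grid))
  phi3 <- interp2(ag, tb$beta_grid, tb$psi3[ord, , drop = FALSE], alpha, abs(beta))
  phi5 <- interp2(ag, tb$beta_grid, tb$psi5[ord, , drop = FALSE], alpha, abs(beta))
  gamma <- (q[4] - q[2]) / phi3
  zeta <- q[3] + gamma * sign(beta) * phi5
  mu <- if (abs(alpha - 1) > 1e-8) zeta - beta * gamma * tan(pi * alpha / 2) else zeta
  structure(list(alpha = alpha, beta = beta, gamma = gamma, mu = mu,
                 n = length(x)),
            class = "alpha_stable_params")
}

#' @export
print.alpha_stable_params <- function(x, ...) {
  cat(sprintf("<alpha_stable_params> alpha=%.3f beta=%.3f gamma=%.4g mu=%.4g (n=%d)\n",
              x$alpha, x$beta, x$gamma, x$mu, x$n))
  invisible(x)
}

#' Approximate brain mask by intensity thresholding
#'
#' Voxels above `fraction` of the volume's 99.5th-percentile intensity.
#' Used to keep air background out of the histogram fit.
#'
#' @param v A [spect_volume()].
#' @param fraction Threshold as a fraction of the robust maximum.
#' @return A [spect_mask()].
#' @export
brain_mask <- function(v, fraction = 0.05) {
  thr <- fraction * stats::quantile(v$data, 0.995, names = FALSE)
  spect_mask(v$data > thr)
}

#' Linear intensity normalization via alpha-stable histogram matching
#'
#' Fits an alpha-stable law to each volume's in-mask intensity histogram,
#' pools the dispersions and locations as `gamma* = mean(gamma_i)`,
#' `mu* = mean(mu_i)`, and maps each volume by `Y = a_i X - b_i` with
#' `a_i = gamma*/gamma_i` and `b_i = a_i mu_i - mu*` — the unique linear map
#' sending `(gamma_i, mu_i)` to `(gamma*, mu*)`. Re-fitting a normalized
#' volume recovers the pooled parameters up to estimator noise.
#'
#' @param volumes List of [spect_volume()] objects.
#' @param masks Optional list of [spect_mask()]s (default: [brain_mask()] of
#'   each volume).
#' @param mask_fraction Threshold passed to [brain_mask()].
#' @return A list with `model` (class `stable_norm_model`: per-image tibble
#'   of fitted parameters and coefficients, plus `gamma_star`, `mu_star`) and
#'   `volumes` (the normalized volumes, same order).
#' @export
normalize_intensity <- function(volumes, masks = NULL, mask_fraction = 0.05) {
  stopifnot(length(volumes) >= 1)
  fits <- vector("list", length(volumes))
  for (i in seq_along(volumes)) {
    m <- if (is.null(masks)) brain_mask(volumes[[i]], mask_fraction) else masks[[i]]
    fits[[i]] <- tryCatch(fit_alpha_stable(volumes[[i]], mask = m),
                          error = function(e)
                            stop("alpha-stable fit failed for image '",
                                 volumes[[i]]$id, "': ", conditionMessage(e),
                                 call. = FALSE))
  }
  gam <- vapply(fits, `[[`, 0, "gamma")
  mu <- vapply(fits, `[[`, 0, "mu")
  gamma_star <- mean(gam)
  mu_star <- mean(mu)
  a <- gamma_star / gam
  b <- a * mu - mu_star
  out <- volumes
  for (i in seq_along(volumes)) out[[i]]$data <- a[i] * volumes[[i]]$data - b[i]
  model <- structure(list(
    gamma_star = gamma_star, mu_star = mu_star,
    per_image = tibble::tibble(
      id = vapply(volumes, `[[`, "", "id"),
      alpha = vapply(fits, `[[`, 0, "alpha"),
      beta = vapply(fits, `[[`, 0, "beta"),
      gamma = gam, mu = mu, a = a, b = b)),
    class = "stable_norm_model")
  list(model = model, volumes = out)
}

#' @export
print.stable_norm_model <- function(x, ...) {
  cat(sprintf("<stable_norm_model> %d images, gamma*=%.4g mu*=%.4g\n",
              nrow(x$per_image), x$gamma_star, x$mu_star))
  print(x$per_image, n = 5)
  invisible(x)
}

#' @rdname normalize_intensity
#' @param x A `stable_norm_model`.
#' @param ... Unused.
#' @export
tidy.stable_norm_model <- function(x, ...) x$per_image

#' @rdname normalize_intensity
#' @export
glance.stable_norm_model <- function(x, ...) {
  tibble::tibble(n_images = nrow(x$per_image),
                 gamma_star = x$gamma_star, mu_star = x$mu_star)
}
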