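# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixtures)) assign(name, fn(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# A healthy (control-like) phantom at default study conditions.
control_phantom <- function(seed = 11) {
  fixture(paste0("control_", seed),
          function() generate_phantom(phantom_spec(seed = seed),
                                      id = paste0("ctl", seed)))
}

# A patient-like phantom with strong asymmetric damage.
pd_phantom <- function() {
  fixture("pd", function()
    generate_phantom(phantom_spec(damage = c(0.8, 0.3), seed = 21), id = "pd"))
}

# Small cohort for plumbing tests (full-size grids, few subjects).
small_cohort <- function() {
  fixture("small_cohort", function()
    generate_cohort(n_pd = 4, n_hc = 3, seed = 5))
}

# Template built from the small cohort's controls.
small_template <- function() {
  fixture("small_template", function() {
    coh <- small_cohort()
    build_template(coh$volume[coh$group == "HC"])
  })
}

# Random rotation matrix (uniform axis, given angle in degrees).
random_rotation <- function(angle_deg) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  striatr:::rotvec_to_matrix(ax * angle_deg * pi / 180)
}

# Uniform surface samples of an ellipsoid (rows of R = principal directions).
ellipsoid_surface_points <- function(n, center, axes, R = diag(3)) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(u, 2, axes, `*`) %*% R + rep(center, each = n)
}

# High-accuracy independent distance oracle: minimize the Euclidean distance
# over the spherical parameterization of the surface, multi-start.
oracle_ellipsoid_distance <- function(p, axes) {
  surf <- function(ang) c(axes[1] * cos(ang[1]) * cos(ang[2]),
                          axes[2] * cos(ang[1]) * sin(ang[2]),
                          axes[3] * sin(ang[1]))
  obj <- function(ang) sum((p - surf(ang))^2)
  best <- Inf
  for (lat in seq(-1.2, 1.2, length.out = 5))
    for (lon in seq(0, 2 * pi, length.out = 7)[-7]) {
      o <- stats::optim(c(lat, lon), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
      best <- min(best, o$value)
    }
  sqrt(best)
}
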