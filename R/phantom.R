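#' Digital DaT-SPECT phantom specification
#'
#' Describes a synthetic brain volume with two high-uptake striatal bodies
#' over a lower-uptake brain background. Each striatum is a "comma": the
#' union of a large body ellipsoid and a smaller tail ellipsoid offset
#' posteriorly along the body's main axis. Disease severity (`damage`, one
#' value per side in \[0, 1\]) reduces uptake, shrinks the tail toward a
#' "dot" shape, and is normally accompanied by an orientation change
#' (`rotation_deg`) of the whole striatum about the axial (z) axis.
#'
#' Defaults emulate a clinical acquisition at desk scale: a 64 x 64 x 48 grid
#' at 2.95 mm isotropic spacing, striatal-to-background contrast 3:1, Poisson
#' count noise at 50 counts per unit intensity and a 10 mm FWHM Gaussian
#' point-spread blur.
#'
#' @param grid_dim Volume dimensions (x = left-right, y = posterior-anterior,
#'   z = inferior-superior).
#' @param spacing Voxel size in mm (isotropic scalar or length 3).
#' @param background_uptake Brain baseline intensity.
#' @param striatal_uptake Healthy striatal intensity (per side, recycled).
#' @param damage Per-side severity in \[0, 1\], `c(left, right)`.
#' @param rotation_deg Per-side orientation change in degrees about z;
#'   defaults to `50 * damage`.
#' @param body_axes,tail_axes Semi-axes of the comma body and tail, voxels.
#' @param tail_offset Distance of tail centre behind the body centre along
#'   the main axis, voxels.
#' @param noise Poisson scale (expected counts per unit intensity); larger is
#'   less noisy.
#' @param psf_fwhm_mm Gaussian blur full width at half maximum, mm.
#' @param seed Integer seed making the phantom deterministic.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dim = c(64, 64, 48), spacing = 2.95,
                         background_uptake = 1, striatal_uptake = 3,
                         damage = c(0, 0), rotation_deg = NULL,
                         body_axes = c(7.5, 4.2, 3.2),
                         tail_axes = c(3.4, 2.6, 2.6),
                         tail_offset = 6.5,
                         noise = 50, psf_fwhm_mm = 10, seed = 17) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  damage <- rep(as.numeric(damage), length.out = 2)
  striatal_uptake <- rep(as.numeric(striatal_uptake), length.out = 2)
  if (any(damage < 0 | damage > 1)) stop("damage must lie in [0, 1]", call. = FALSE)
  if (background_uptake <= 0 || any(striatal_uptake <= 0))
    stop("uptake values must be positive", call. = FALSE)
  if (psf_fwhm_mm < 0) stop("psf_fwhm_mm must be >= 0", call. = FALSE)
  if (is.null(rotation_deg)) rotation_deg <- 50 * damage
  rotation_deg <- rep(as.numeric(rotation_deg), length.out = 2)
  structure(list(grid_dim = as.integer(grid_dim), spacing = spacing,
                 background_uptake = background_uptake,
                 striatal_uptake = striatal_uptake,
                 damage = damage, rotation_deg = rotation_deg,
                 body_axes = body_axes, tail_axes = tail_axes,
                 tail_offset = tail_offset,
                 noise = noise, psf_fwhm_mm = psf_fwhm_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Voxels (1-based index grid) inside an ellipsoid: center (voxels),
# semi-axes (voxels), rows of R are the principal directions.
ellipsoid_voxels <- function(dim, center, axes, R) {
  gx <- seq_len(dim[1]); gy <- seq_len(dim[2]); gz <- seq_len(dim[3])
  q <- array(FALSE, dim)
  # evaluate per z-slab to keep memory flat
  for (k in gz) {
    P <- cbind(rep(gx - center[1], dim[2]),
               rep(gy - center[2], each = dim[1]),
               k - center[3])
    Q <- P %*% t(R)
    q[, , k] <- (Q[, 1] / axes[1])^2 + (Q[, 2] / axes[2])^2 +
      (Q[, 3] / axes[3])^2 <= 1
  }
  q
}

# Separable Gaussian blur with edge-clamped, column-normalized kernels:
# the total count is preserved exactly.
gaussian_blur <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (o in seq(-r, r)) {
      tgt <- pmin(pmax(seq_len(n) + o, 1L), n)
      K[cbind(tgt, seq_len(n))] <- K[cbind(tgt, seq_len(n))] + w[o + r + 1]
    }
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = n)
    m <- K %*% m
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  arr
}

#' Generate a synthetic DaT-SPECT phantom with ground truth
#'
#' Builds the noiseless "ideal" intensity map (brain background plus two
#' striatal commas at the programmed uptake), draws Poisson counts at the
#' requested noise scale, applies the Gaussian point-spread blur and rescales
#' back to intensity units. Ground truth stores the pre-noise striatal masks,
#' the programmed orientations and mean uptakes, and the implied
#' shape-modulated uptake used by the clinical-score link.
#'
#' @param spec A [phantom_spec()].
#' @param id Subject identifier for the generated volume.
#' @return A list with elements `volume` (a [spect_volume()]) and `truth`
#'   (per-side masks, orientation matrices, rotation, programmed uptake,
#'   dysmorphism and shape-modulated uptake).
#' @export
generate_phantom <- function(spec = phantom_spec(), id = "phantom") {
  d <- spec$grid_dim
  ctr <- (d + 1) / 2
  brain_axes <- pmin(c(0.42, 0.46, 0.42) * d, (d - 3) / 2)
  brain <- ellipsoid_voxels(d, ctr, brain_axes, diag(3))

  ideal <- array(0, d)
  ideal[brain] <- spec$background_uptake

  truth <- list()
  for (s in 1:2) {        # 1 = left (world +x), 2 = right
    side <- c("left", "right")[s]
    sgn <- if (s == 1) 1 else -1
    # baseline main axis: tilted 30 degrees from anterior-posterior toward
    # the midline, mirrored between hemispheres
    base <- rot_z(sgn * -30)
    R <- rot_z(sgn * spec$rotation_deg[s]) %*% base
    # principal directions as rows: main axis = rotated y (posterior-anterior),
    # second = rotated x, third = z
    dirs <- t(R)[c(2, 1, 3), , drop = FALSE]
    c_str <- ctr + c(sgn * 0.133 * d[1], 0.023 * d[2], 0)
    if (any(c_str - max(spec$body_axes) < 1) || any(c_str + max(spec$body_axes) > d))
      stop("striatum geometry falls outside the grid", call. = FALSE)
    body <- ellipsoid_voxels(d, c_str, spec$body_axes, dirs)
    tail_scale <- 1 - spec$damage[s]
    tail_ctr <- c_str - spec$tail_offset * dirs[1, ]
    m <- body
    if (tail_scale > 0.05) {
      tl <- ellipsoid_voxels(d, tail_ctr, spec$tail_axes * tail_scale, dirs)
      m <- m | tl
    }
    if (any(m & !brain))
      stop("striatum geometry falls outside the brain", call. = FALSE)
    uptake <- spec$striatal_uptake[s] * (1 - 0.6 * spec$damage[s])
    ideal[m] <- uptake
    th <- spec$rotation_deg[s] * pi / 180
    di_true <- 1 - cos(th)^2
    truth[[side]] <- list(mask = spect_mask(m, side = side),
                          orientation = dirs,
                          rotation_deg = spec$rotation_deg[s],
                          mean_uptake = uptake,
                          di = di_true,
                          smu = uptake * (1 - di_true))
  }

  vol_data <- with_seed(spec$seed, {
    counts <- array(stats::rpois(length(ideal), spec$noise * ideal), d)
    counts / spec$noise
  })
  sigma_vox <- (spec$psf_fwhm_mm / (2 * sqrt(2 * log(2)))) / spec$spacing
  vol_data <- gaussian_blur(vol_data, sigma_vox)

  list(volume = spect_volume(vol_data, spacing = spec$spacing, id = id),
       truth = truth)
}

#' Generate a synthetic subject cohort with linked clinical scores
#'
#' Emulates a case-control DaT-SPECT study: controls carry at most trace
#' damage (uniform on \[0, 0.1\] per side) while patients have a dominant
#' side with damage uniform over `severity_range` and a contralateral side at
#' 30-80% of that (unilateral onset). Motor scores follow a monotone link
#' with the programmed shape-modulated uptake: each side's score is
#' `c0/2 - c1/2 * SMU_contralateral` plus Gaussian noise, clipped at zero,
#' and the total score is their sum, so higher striatal damage means worse
#' motor impairment.
#'
#' @param n_pd,n_hc Number of patient-like and control-like subjects.
#' @param severity_range Dominant-side damage interval for patients.
#' @param seed Integer seed; the cohort (volumes and clinical table) is fully
#'   reproducible from it.
#' @param spec_args Named list of overrides passed to [phantom_spec()]
#'   (e.g. a smaller grid for quick tests).
#' @param link Clinical link parameters `c(c0, c1, sd)` of
#'   `UPDRS = c0 - c1 * mean(SMU_true) + noise`.
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (`"PD"`/`"HC"`), list-columns `volume` and `truth`, per-side damage, and
#'   clinical columns `updrs_me`, `updrs_me_left`, `updrs_me_right`, `hy`,
#'   `duration_years` (NA for controls). Row order is shuffled.
#' @export
generate_cohort <- function(n_pd = 31, n_hc = 12, severity_range = c(0.5, 0.9),
                            seed = 7, spec_args = list(),
                            link = c(c0 = 45, c1 = 8, sd = 5)) {
  if (n_pd < 1 || n_hc < 1) stop("counts must be >= 1", call. = FALSE)
  if (length(severity_range) != 2 || diff(severity_range) < 0 ||
      any(severity_range < 0 | severity_range > 1))
    stop("invalid severity range", call. = FALSE)

  n <- n_pd + n_hc
  plan <- with_seed(seed, {
    group <- c(rep("PD", n_pd), rep("HC", n_hc))
    dmg <- matrix(0, n, 2)
    dominant <- sample(c("left", "right"), n, replace = TRUE)
    for (i in seq_len(n)) {
      if (group[i] == "PD") {
        dom <- stats::runif(1, severity_range[1], severity_range[2])
        oth <- dom * stats::runif(1, 0.3, 0.8)
        dmg[i, ] <- if (dominant[i] == "left") c(dom, oth) else c(oth, dom)
      } else {
        dmg[i, ] <- stats::runif(2, 0, 0.1)
      }
    }
    list(group = group, dmg = dmg, dominant = dominant,
         order = sample.int(n),
         subseeds = sample.int(2^30, n),
         clinseed = sample.int(2^30, 1))
  })

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sa <- c(list(damage = plan$dmg[i, ], seed = plan$subseeds[i]), spec_args)
    ph <- generate_phantom(do.call(phantom_spec, sa),
                           id = sprintf("S%03d", i))
    rows[[i]] <- ph
  }

  smu_l <- vapply(rows, function(r) r$truth$left$smu, 0)
  smu_r <- vapply(rows, function(r) r$truth$right$smu, 0)
  clin <- with_seed(plan$clinseed, {
    c0 <- link[["c0"]]; c1 <- link[["c1"]]; sdv <- link[["sd"]]
    # left body side symptoms reflect the contralateral (right) striatum
    u_left <- pmax(0, c0 / 2 - (c1 / 2) * smu_r + stats::rnorm(n, 0, sdv / sqrt(2)))
    u_right <- pmax(0, c0 / 2 - (c1 / 2) * smu_l + stats::rnorm(n, 0, sdv / sqrt(2)))
    dom_dmg <- pmax(plan$dmg[, 1], plan$dmg[, 2])
    hy <- pmin(4, pmax(1, round(1 + 3 * (dom_dmg - 0.4))))
    dur <- pmax(0.5, 2 + 10 * (dom_dmg - 0.4) + stats::rnorm(n, 0, 1))
    list(u_left = u_left, u_right = u_right, hy = hy, dur = dur)
  })

  tb <- tibble::tibble(
    subject_id = vapply(rows, function(r) r$volume$id, ""),
    group = plan$group,
    volume = lapply(rows, `[[`, "volume"),
    truth = lapply(rows, `[[`, "truth"),
    damage_left = plan$dmg[, 1],
    damage_right = plan$dmg[, 2],
    dominant_side = plan$dominant,
    updrs_me_left = ifelse(plan$group == "PD", round(clin$u_left, 1), NA_real_),
    updrs_me_right = ifelse(plan$group == "PD", round(clin$u_right, 1), NA_real_),
    hy = ifelse(plan$group == "PD", clin$hy, NA_real_),
    duration_years = ifelse(plan$group == "PD", round(clin$dur, 1), NA_real_)
  )
  tb$updrs_me <- tb$updrs_me_left + tb$updrs_me_right
  tb[plan$order, ]
}
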