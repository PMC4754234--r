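# Per-subject uptake and shape features: MEU (mean ellipsoid uptake),
# DI (dysmorphic index), SMU = MEU * (1 - DI), and the classical SBR.

#' Mean ellipsoid uptake
#'
#' Arithmetic mean of the (intensity-normalized) volume over an ROI.
#'
#' @param v A [spect_volume()].
#' @param roi A non-empty [spect_mask()].
#' @return The mean intensity.
#' @export
compute_meu <- function(v, roi) {
  dat <- if (inherits(roi, "spect_mask")) roi$data else roi
  if (!any(dat)) stop("ROI is empty", call. = FALSE)
  mean(v$data[dat])
}

#' Dysmorphic index between a subject and the template ellipsoid
#'
#' `DI = 1 - prod_i |E_i^S . E_i^T|` over the three rank-paired unit
#' eigenvectors (principal directions ordered by descending semi-axis) of
#' the subject and template striatal ellipsoids. 0 means identical
#' orientation; 1 means at least one principal direction is orthogonal to
#' its template counterpart.
#'
#' @param subject,template [ellipsoid()] objects.
#' @return DI in \[0, 1\], with attribute `degenerate_axes = TRUE` when
#'   adjacent semi-axes of either ellipsoid differ by less than 2% (the rank
#'   pairing is then unstable).
#' @export
compute_di <- function(subject, template) {
  stopifnot(inherits(subject, "ellipsoid"), inherits(template, "ellipsoid"))
  Es <- subject$orientation / sqrt(rowSums(subject$orientation^2))
  Et <- template$orientation / sqrt(rowSums(template$orientation^2))
  di <- 1 - prod(abs(rowSums(Es * Et)))
  di <- min(max(di, 0), 1)
  near <- function(a) any(a[-3] / a[-1] < 1.02)
  if (near(subject$semi_axes) || near(template$semi_axes)) {
    warning("near-degenerate semi-axes: eigenvector pairing may be unstable")
    attr(di, "degenerate_axes") <- TRUE
  }
  di
}

#' Shape-modulated uptake
#'
#' `SMU = MEU * (1 - DI)`: uptake discounted by shape dysmorphism.
#'
#' @param meu Mean ellipsoid uptake.
#' @param di Dysmorphic index in \[0, 1\].
#' @return The SMU value.
#' @export
compute_smu <- function(meu, di) {
  if (any(di < 0 | di > 1)) stop("DI must lie in [0, 1]", call. = FALSE)
  meu * (1 - di)
}

#' Specific binding ratio
#'
#' `SBR = (C_str - C_occ) / C_occ` with `C_str`, `C_occ` the mean counts in
#' the striatal and occipital (reference) ROIs.
#'
#' @param v A [spect_volume()].
#' @param striatal_roi,occipital_roi Non-empty [spect_mask()]s.
#' @return The SBR value.
#' @export
compute_sbr <- function(v, striatal_roi, occipital_roi) {
  c_str <- compute_meu(v, striatal_roi)
  c_occ <- compute_meu(v, occipital_roi)
  if (c_occ <= 0)
    stop("occipital reference mean must be positive", call. = FALSE)
  (c_str - c_occ) / c_occ
}

#' Default occipital reference ROI in template space
#'
#' A fixed box over the posterior-inferior part of the brain, clipped to the
#' brain mask — an automated stand-in for a manually placed occipital ROI.
#'
#' @param template Template [spect_volume()].
#' @param mask_fraction Brain-mask threshold fraction.
#' @return A [spect_mask()].
#' @export
occipital_roi <- function(template, mask_fraction = 0.05) {
  d <- dim(template$data)
  bm <- brain_mask(template, mask_fraction)$data
  box <- array(FALSE, d)
  ys <- seq_len(max(1, round(0.18 * d[2])))             # posterior = low y
  zs <- seq(max(1, round(0.35 * d[3])), round(0.6 * d[3]))
  xs <- seq(round(0.3 * d[1]), round(0.7 * d[1]))
  box[xs, ys, zs] <- TRUE
  m <- box & bm
  if (!any(m)) stop("occipital reference box misses the brain", call. = FALSE)
  spect_mask(m)
}

#' Template striatal ellipsoids
#'
#' Runs segmentation and ellipsoid fitting on the template volume itself;
#' the resulting per-side ellipsoids are the DI reference.
#'
#' @param template Template [spect_volume()].
#' @param seed Segmentation seed.
#' @return List with `left` and `right` [ellipsoid()]s.
#' @export
template_ellipsoids <- function(template, seed = 17) {
  seg <- segment_striata(template, template, seed = seed)
  list(left = fit_ellipsoid(mask_surface_points(seg$left))$ellipsoid,
       right = fit_ellipsoid(mask_surface_points(seg$right))$ellipsoid)
}

#' Extract the per-subject feature record
#'
#' Fits a per-side ellipsoid to the segmented striatal masks, then computes
#' MEU over the ellipsoid ROI, DI against the matching-side template
#' ellipsoid, SMU = MEU * (1 - DI), and (when an occipital reference is
#' given) the SBR per side. A side whose fit fails is flagged and its
#' features set to NA.
#'
#' @param v Intensity-normalized [spect_volume()] in template space.
#' @param seg A `segmentation_result` for `v`.
#' @param template_ells Per-side template ellipsoids
#'   (see [template_ellipsoids()]).
#' @param occipital Optional occipital reference [spect_mask()] enabling SBR.
#' @return One-row tibble: `subject_id`, `meu_l`, `meu_r`, `di_l`, `di_r`,
#'   `smu_l`, `smu_r`, `sbr_l`, `sbr_r`, `flags`.
#' @export
extract_features <- function(v, seg, template_ells, occipital = NULL) {
  side_feats <- function(side) {
    mask <- seg[[side]]
    tryCatch({
      fit <- fit_ellipsoid(mask_surface_points(mask))
      roi <- ellipsoid_roi(fit$ellipsoid, v, side = side)
      meu <- compute_meu(v, roi)
      di <- suppressWarnings(as.numeric(compute_di(fit$ellipsoid,
                                                   template_ells[[side]])))
      sbr <- if (!is.null(occipital)) compute_sbr(v, mask, occipital) else NA_real_
      list(meu = meu, di = di, smu = compute_smu(meu, di), sbr = sbr, flag = "")
    }, error = function(e) list(meu = NA_real_, di = NA_real_, smu = NA_real_,
                                sbr = NA_real_, flag = side))
  }
  L <- side_feats("left")
  R <- side_feats("right")
  tibble::tibble(subject_id = v$id,
                 meu_l = L$meu, meu_r = R$meu,
                 di_l = L$di, di_r = R$di,
                 smu_l = L$smu, smu_r = R$smu,
                 sbr_l = L$sbr, sbr_r = R$sbr,
                 flags = trimws(paste(L$flag, R$flag)))
}
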