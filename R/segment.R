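# Unsupervised striatal segmentation: per hemisphere, fit a two-component
# 4-D GMM over (intensity, x, y, z) brain voxels, label by maximum
# likelihood, and keep the largest 26-connected high-uptake component.

# Largest 26-connected component of a logical 3-D array, via the voxel
# adjacency graph.
largest_cc <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(mask)
  if (length(idx) == 1) return(mask)
  ijk <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  inside <- array(0L, d)
  inside[idx] <- seq_along(idx)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    nb <- ijk + rep(offs[r, ], each = nrow(ijk))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    tgt <- inside[nb[ok, , drop = FALSE]]
    src <- seq_along(idx)[ok]
    keep <- tgt > 0L
    if (any(keep)) edges[[r]] <- cbind(src[keep], tgt[keep])
  }
  E <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(E, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  out <- array(FALSE, d)
  out[idx[comp$membership == big]] <- TRUE
  out
}

# Voxel features (intensity, i, j, k) for the in-mask voxels of a hemisphere.
voxel_features <- function(v, keep) {
  idx <- which(keep)
  cbind(v$data[idx], arrayInd(idx, dim(v$data)))
}

#' Segment the left and right striatum
#'
#' Splits the brain at the template mid-sagittal plane and, per hemisphere,
#' describes every brain-mask voxel by the 4-vector (normalized intensity,
#' x, y, z), fits a two-component Gaussian mixture by EM, labels voxels by
#' maximum likelihood, and keeps the largest 26-connected component of the
#' high-uptake class as that side's striatal mask. Fully unsupervised; no
#' per-subject thresholds.
#'
#' @param v [spect_volume()] already registered to the template frame.
#' @param template Template [spect_volume()] defining the mid-plane (defaults
#'   to `v` itself, whose grid is assumed template-aligned).
#' @param seed EM initialization seed.
#' @param mask_fraction Brain-mask threshold fraction (see [brain_mask()]).
#' @param weighted Labeling rule: `TRUE` (default) weighs each component's
#'   likelihood by its mixing proportion (MAP labeling), which keeps the
#'   rare striatal component from annexing its partial-volume halo;
#'   `FALSE` uses the unweighted component-likelihood rule of
#'   [label_voxels()].
#' @return A `segmentation_result`: masks `left`, `right`
#'   ([spect_mask()]), fitted `model_left`, `model_right` and per-side final
#'   log-likelihood `loglik`.
#' @export
segment_striata <- function(v, template = v, seed = 17, mask_fraction = 0.05,
                            weighted = TRUE) {
  bm <- brain_mask(v, mask_fraction)$data
  if (!any(bm) || stats::sd(v$data[bm]) == 0)
    stop("volume has no segmentable structure", call. = FALSE)
  ax <- lr_axis(template)
  n_ax <- dim(template$data)[ax]
  # world-x sign of each index along the left-right axis decides the side
  probe0 <- probe1 <- rep(1, 3)
  probe1[ax] <- n_ax
  x0 <- vox_to_world(template, matrix(probe0, 1))[1]
  x1 <- vox_to_world(template, matrix(probe1, 1))[1]
  lo_half <- seq_len(floor(n_ax / 2))                # lower-index half
  lo_is_left <- x0 > x1                              # left = world +x
  out <- list()
  for (side in c("left", "right")) {
    keep <- bm
    take_lo <- (side == "left") == lo_is_left
    sl <- slice.index(keep, ax)
    keep <- keep & if (take_lo) sl <= max(lo_half) else sl > max(lo_half)
    if (sum(keep) <= 80)
      stop("too few brain voxels in ", side, " hemisphere", call. = FALSE)
    X <- voxel_features(v, keep)
    model <- fit_gmm_em(X, M = 2, seed = seed, init = "intensity")
    lab <- label_voxels(X, model, weighted = weighted)
    hi <- striatal_component(model)
    sel <- lab == hi
    if (!any(sel))
      stop("empty high-uptake segmentation in ", side, " hemisphere",
           call. = FALSE)
    m <- array(FALSE, dim(v$data))
    m[which(keep)[sel]] <- TRUE
    m <- largest_cc(m)
    if (!any(m))
      stop("empty high-uptake segmentation in ", side, " hemisphere",
           call. = FALSE)
    out[[side]] <- list(mask = spect_mask(m, side = side), model = model,
                        loglik = utils::tail(attr(model, "loglik"), 1))
  }
  structure(list(left = out$left$mask, right = out$right$mask,
                 model_left = out$left$model, model_right = out$right$model,
                 loglik = c(left = out$left$loglik, right = out$right$loglik)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> left: %d voxels, right: %d voxels\n",
              sum(x$left$data), sum(x$right$data)))
  invisible(x)
}

#' Dice overlap between two masks
#'
#' @param a,b [spect_mask()] objects (or logical arrays) of identical shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  da <- if (inherits(a, "spect_mask")) a$data else a
  db <- if (inherits(b, "spect_mask")) b$data else b
  stopifnot(identical(dim(da), dim(db)))
  2 * sum(da & db) / (sum(da) + sum(db))
}
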