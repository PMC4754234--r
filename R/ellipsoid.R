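# Ellipsoid shape proxy for a segmented striatum: (X-U)' R' D R (X-U) = 1
# with centre U, orthonormal orientation R (rows = principal directions,
# ordered by descending semi-axis) and D = diag(1/semi_axes^2). Fitted by
# minimizing the sum of squared geometric point-to-surface distances.

#' Ellipsoid
#'
#' @param center Centre, length-3 numeric (voxel or world units).
#' @param semi_axes Three positive semi-axis lengths; stored descending.
#' @param orientation 3 x 3 orthonormal matrix, row i the unit direction of
#'   semi-axis i. Canonicalized: axes sorted descending, first two rows
#'   sign-fixed (largest-magnitude entry positive), third row their cross
#'   product so that the determinant is +1.
#' @return An object of class `ellipsoid`.
#' @export
ellipsoid <- function(center, semi_axes, orientation = diag(3)) {
  center <- as.numeric(center)
  semi_axes <- as.numeric(semi_axes)
  orientation <- as.matrix(orientation)
  stopifnot(length(center) == 3, length(semi_axes) == 3,
            identical(dim(orientation), c(3L, 3L)))
  if (any(semi_axes <= 0)) stop("semi-axes must be positive", call. = FALSE)
  if (max(abs(orientation %*% t(orientation) - diag(3))) > 1e-6)
    stop("orientation must be orthonormal", call. = FALSE)
  ord <- order(semi_axes, decreasing = TRUE)
  semi_axes <- semi_axes[ord]
  R <- orientation[ord, , drop = FALSE]
  for (i in 1:2) {
    j <- which.max(abs(R[i, ]))
    if (R[i, j] < 0) R[i, ] <- -R[i, ]
  }
  R[3, ] <- c(R[1, 2] * R[2, 3] - R[1, 3] * R[2, 2],
              R[1, 3] * R[2, 1] - R[1, 1] * R[2, 3],
              R[1, 1] * R[2, 2] - R[1, 2] * R[2, 1])
  structure(list(center = center, semi_axes = semi_axes, orientation = R),
            class = "ellipsoid")
}

#' @export
print.ellipsoid <- function(x, ...) {
  cat(sprintf("<ellipsoid> centre=(%.2f, %.2f, %.2f) semi-axes=(%.2f, %.2f, %.2f)\n",
              x$center[1], x$center[2], x$center[3],
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  invisible(x)
}

#' Surface voxels of a binary mask
#'
#' Mask voxels with at least one six-connected background neighbour
#' (out-of-grid counts as background).
#'
#' @param m A [spect_mask()] (or logical array).
#' @param spacing Optional per-axis scale applied to the returned
#'   coordinates (defaults to pure 1-based voxel indices).
#' @return Numeric matrix, one surface point per row.
#' @export
mask_surface_points <- function(m, spacing = c(1, 1, 1)) {
  dat <- if (inherits(m, "spect_mask")) m$data else m
  if (!any(dat)) stop("mask is empty", call. = FALSE)
  d <- dim(dat)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- dat
  interior <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- dat & !interior
  pts <- arrayInd(which(surf), d)
  sweep(pts, 2, as.numeric(spacing), `*`)
}

# Distances from rows of P (principal-frame coordinates, ellipsoid centred at
# origin and axis-aligned with semi-axes a) to the ellipsoid surface.
# For each point the nearest surface point solves x_i = a_i^2 p_i/(t + a_i^2)
# where t is the unique root of F(t) = sum (a_i p_i / (t + a_i^2))^2 - 1
# above the largest pole; F is convex and decreasing there, so Newton from a
# bracketing start converges monotonically.
principal_frame_distance <- function(P, a) {
  n <- nrow(P)
  eps <- 1e-12
  A2 <- matrix(a^2, n, 3, byrow = TRUE)
  AP <- sweep(abs(P), 2, a, `*`)                 # |a_i p_i|
  nz <- abs(P) > eps
  # pole: largest -a_i^2 among axes with p_i != 0
  pole <- apply(ifelse(nz, -A2, -Inf), 1, max)
  S <- sqrt(rowSums(AP^2))
  degenerate <- S < eps                          # at the centre
  t0 <- pmax(S - apply(A2, 1, max), pole + 1e-9 * max(a)^2 + eps)
  t <- t0
  for (iter in 1:100) {
    denom <- t + A2
    Fv <- rowSums(ifelse(nz, (AP / denom)^2, 0)) - 1
    dF <- -2 * rowSums(ifelse(nz, AP^2 / denom^3, 0))
    step <- ifelse(degenerate, 0, Fv / dF)
    t_new <- t - step
    t_new <- pmax(t_new, (t + pole) / 2)         # stay above the pole
    if (max(abs(t_new - t), na.rm = TRUE) < 1e-14 * max(a)^2) {
      t <- t_new
      break
    }
    t <- t_new
  }
  X <- A2 * P / (t + A2)
  dist <- sqrt(rowSums((P - X)^2))
  dist[degenerate] <- min(a)
  dist
}

#' Euclidean distance from a point to an ellipsoid surface
#'
#' Exact geometric distance computed in the principal frame by robust 1-D
#' root finding (Newton on the convex decreasing orthogonality function).
#' Works for points inside and outside; the centre maps to the smallest
#' semi-axis.
#'
#' @param p Length-3 point, or a matrix of points (one per row).
#' @param e An [ellipsoid()].
#' @return Distance(s), >= 0.
#' @export
point_ellipsoid_distance <- function(p, e) {
  P <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  Q <- (P - rep(e$center, each = nrow(P))) %*% t(e$orientation)
  d <- principal_frame_distance(Q, e$semi_axes)
  if (is.matrix(p)) d else d[1]
}

# Moment-based initial ellipsoid from a point cloud.
moment_ellipsoid <- function(pts) {
  ctr <- colMeans(pts)
  C <- stats::cov(pts)
  eg <- eigen(C, symmetric = TRUE)
  axes <- sqrt(pmax(2 * eg$values, 1e-6))
  R <- t(eg$vectors)
  # rescale so the mean normalized radius is 1
  Q <- (pts - rep(ctr, each = nrow(pts))) %*% t(R)
  r <- sqrt(rowSums(sweep(Q, 2, axes, `/`)^2))
  axes <- axes * mean(r)
  ellipsoid(ctr, axes, R)
}

#' Fit an ellipsoid to a point cloud by geometric least squares
#'
#' Minimizes the sum of squared geometric distances from the points to the
#' ellipsoid surface over centre, orientation (axis-angle) and semi-axes,
#' using Levenberg-Marquardt from a moment-based initializer (centroid,
#' covariance eigenvectors, RMS-scaled axes).
#'
#' @param points Numeric matrix of surface points (>= 10, non-coplanar).
#' @param max_iter Maximum optimizer iterations.
#' @return A list: `ellipsoid` and `report` (class `ellipsoid_fit_report`
#'   with `final_energy`, `n_points`, `iterations`, `converged`).
#' @export
fit_ellipsoid <- function(points, max_iter = 200) {
  pts <- as.matrix(points)
  if (nrow(pts) < 10) stop("ellipsoid fit needs at least 10 points", call. = FALSE)
  sv <- svd(scale(pts, scale = FALSE))$d
  if (sv[3] < 1e-8 * sv[1])
    stop("degenerate (coplanar) point set", call. = FALSE)
  init <- moment_ellipsoid(pts)
  R0 <- init$orientation
  par0 <- c(init$center, 0, 0, 0, log(init$semi_axes))
  resid_fn <- function(par) {
    ctr <- par[1:3]
    R <- rotvec_to_matrix(par[4:6]) %*% R0
    a <- exp(par[7:9])
    Q <- (pts - rep(ctr, each = nrow(pts))) %*% t(R)
    principal_frame_distance(Q, a)
  }
  e0 <- sum(resid_fn(par0)^2)
  fit <- minpack.lm::nls.lm(par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-10))
  par <- fit$par
  energy <- sum(resid_fn(par)^2)
  converged <- fit$info %in% 1:4
  if (energy > e0) {        # never worse than the initializer
    par <- par0
    energy <- e0
    converged <- FALSE
  }
  R <- rotvec_to_matrix(par[4:6]) %*% R0
  # re-orthonormalize against accumulated round-off
  s <- svd(R)
  R <- s$u %*% t(s$v)
  e <- ellipsoid(par[1:3], exp(par[7:9]), R)
  report <- structure(list(final_energy = energy, n_points = nrow(pts),
                           iterations = fit$niter, converged = converged),
                      class = "ellipsoid_fit_report")
  list(ellipsoid = e, report = report)
}

#' @export
print.ellipsoid_fit_report <- function(x, ...) {
  cat(sprintf("<ellipsoid_fit_report> energy=%.4g over %d points, %d iterations, converged=%s\n",
              x$final_energy, x$n_points, x$iterations, x$converged))
  invisible(x)
}

#' Voxel mask of an ellipsoid interior on a volume grid
#'
#' Marks voxels whose centres satisfy `(X-U)' R' D R (X-U) <= 1`, with voxel
#' coordinates scaled by `spacing` to match the frame the ellipsoid was
#' fitted in.
#'
#' @param e An [ellipsoid()].
#' @param grid A [spect_volume()] supplying the grid.
#' @param spacing Per-axis coordinate scale (1 = pure voxel indices).
#' @param side Side tag for the returned mask.
#' @return A [spect_mask()]; error if no voxel centre falls inside.
#' @export
ellipsoid_roi <- function(e, grid, spacing = c(1, 1, 1), side = "none") {
  d <- dim(grid$data)
  m <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    P <- cbind(rep(seq_len(d[1]) * spacing[1], d[2]),
               rep(seq_len(d[2]) * spacing[2], each = d[1]),
               k * spacing[3])
    Q <- (P - rep(e$center, each = nrow(P))) %*% t(e$orientation)
    m[, , k] <- rowSums(sweep(Q, 2, e$semi_axes, `/`)^2) <= 1
  }
  if (!any(m)) stop("ellipsoid does not intersect the grid", call. = FALSE)
  spect_mask(m, side = side)
}
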