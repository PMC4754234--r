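# Rigid (6-DOF) registration by normalized-correlation maximization with a
# multi-resolution Nelder-Mead search. Self-contained: no external binary.

# Rodrigues: axis-angle 3-vector -> rotation matrix.
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Inverse Rodrigues.
matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  th <- acos(min(max(ct, -1), 1))
  if (th < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}

#' Rigid transform (rotation + translation)
#'
#' @param rotation Axis-angle rotation vector, radians.
#' @param translation Translation in mm (applied in world space after
#'   rotating about the fixed volume's world centre).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0)) {
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot=(%.4f, %.4f, %.4f) rad  t=(%.2f, %.2f, %.2f) mm\n",
              x$rotation[1], x$rotation[2], x$rotation[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# World centre of a volume (world coordinates of the central voxel).
world_center <- function(v) {
  as.numeric(v$affine[1:3, , drop = FALSE] %*% c((dim(v$data) - 1) / 2, 1))
}

#' Resample a volume onto a fixed grid under a rigid transform
#'
#' The transform maps fixed-frame world coordinates into the moving volume's
#' world frame: `w_m = R (w_f - c) + c + t`, with `c` the fixed volume's
#' world centre. Trilinear interpolation; zero outside the field of view.
#'
#' @param moving,fixed [spect_volume()] objects.
#' @param transform A [rigid_transform()].
#' @return The moving volume resampled on the fixed grid.
#' @export
resample_rigid <- function(moving, fixed, transform = rigid_transform()) {
  R <- rotvec_to_matrix(transform$rotation)
  cc <- world_center(fixed)
  # homogeneous world transform fixed -> moving
  Tw <- diag(4)
  Tw[1:3, 1:3] <- R
  Tw[1:3, 4] <- cc + transform$translation - R %*% cc
  M <- solve(moving$affine) %*% Tw %*% fixed$affine
  dat <- resample_affine_cpp(as.numeric(moving$data), dim(moving$data),
                             dim(fixed$data), M[1:3, , drop = FALSE])
  spect_volume(array(dat, dim(fixed$data)), spacing = fixed$spacing,
               affine = fixed$affine, id = moving$id)
}

# Block-average downsampling by an integer factor (for the pyramid).
downsample_volume <- function(v, f) {
  if (f == 1L) return(v)
  d <- dim(v$data)
  nd <- d %/% f
  dat <- v$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f), drop = FALSE]
  dat <- array(dat, c(f, nd[1], f, nd[2], f, nd[3]))
  dat <- apply(dat, c(2, 4, 6), mean)
  aff <- v$affine
  aff[, 1:3] <- aff[, 1:3] * rep(f, each = 4)
  aff[1:3, 4] <- aff[1:3, 4] + v$affine[1:3, 1:3] %*% rep((f - 1) / 2, 3)
  spect_volume(dat, spacing = v$spacing * f, affine = aff, id = v$id)
}

ncc <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

#' Rigid 6-DOF registration of two volumes
#'
#' Maximizes the normalized correlation between the resampled moving volume
#' and the fixed volume over rotations and translations, coarse to fine over
#' a block-averaged pyramid, with a derivative-free simplex search started
#' at the identity.
#'
#' @param moving,fixed [spect_volume()] objects (non-constant).
#' @param levels Pyramid depth (downsampling factors `2^(levels-1), ..., 1`).
#' @param max_iter Simplex iterations per pyramid level.
#' @return A list: `transform` ([rigid_transform()]), `resampled` (moving on
#'   the fixed grid), `ncc` (final similarity), `converged`.
#' @export
register_rigid <- function(moving, fixed, levels = 3, max_iter = 400) {
  if (stats::sd(moving$data) == 0 || stats::sd(fixed$data) == 0)
    stop("cannot register a constant image", call. = FALSE)
  par <- rep(0, 6)
  conv <- 0L
  for (lev in seq(levels, 1)) {
    f <- 2L^(lev - 1L)
    mv <- downsample_volume(moving, f)
    fx <- downsample_volume(fixed, f)
    fdat <- as.numeric(fx$data)
    obj <- function(p) {
      tr <- rigid_transform(p[1:3], p[4:6])
      -ncc(as.numeric(resample_rigid(mv, fx, tr)$data), fdat)
    }
    res <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-7,
                                       parscale = c(rep(0.05, 3), rep(2, 3))))
    par <- res$par
    conv <- res$convergence
  }
  if (conv != 0L)
    warning("registration simplex did not fully converge; returning best transform")
  tr <- rigid_transform(par[1:3], par[4:6])
  out <- resample_rigid(moving, fixed, tr)
  list(transform = tr, resampled = out,
       ncc = ncc(as.numeric(out$data), as.numeric(fixed$data)),
       converged = conv == 0L)
}

#' Build a symmetric control-group template
#'
#' Registers every control volume to a running mean (two refinement passes),
#' averages the co-registered volumes, and symmetrizes the result by
#' averaging with its own mid-plane reflection. The returned template equals
#' its reflection bit-exactly.
#'
#' @param controls List of at least two control [spect_volume()]s.
#' @param iterations Register-and-average refinement passes.
#' @param levels,max_iter Passed to [register_rigid()].
#' @return A [spect_volume()] template.
#' @export
build_template <- function(controls, iterations = 2, levels = 3, max_iter = 400) {
  if (length(controls) < 2)
    stop("template construction needs at least 2 control volumes", call. = FALSE)
  ref <- controls[[1]]
  avg <- NULL
  for (it in seq_len(iterations)) {
    reg <- lapply(controls, function(v) register_rigid(v, ref, levels, max_iter)$resampled)
    dat <- Reduce(`+`, lapply(reg, `[[`, "data")) / length(reg)
    avg <- spect_volume(dat, spacing = ref$spacing, affine = ref$affine,
                        id = "template")
    ref <- avg
  }
  sym <- (avg$data + reflect_midplane(avg)$data) / 2
  spect_volume(sym, spacing = avg$spacing, affine = avg$affine, id = "template")
}
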