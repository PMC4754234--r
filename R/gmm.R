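# Two-component 4-D Gaussian mixture over voxel vectors
# x = (intensity, i, j, k), fitted by EM, with maximum-likelihood labeling.

#' Gaussian mixture model over 4-D voxel features
#'
#' @param weights Mixing weights, non-negative, summing to 1.
#' @param means List (or d x M matrix columns) of component mean vectors.
#' @param covariances List of d x d symmetric positive-definite matrices.
#' @return An object of class `gmm_model`.
#' @export
gmm_model <- function(weights, means, covariances) {
  weights <- as.numeric(weights)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  if (is.matrix(means)) means <- lapply(seq_len(ncol(means)), function(i) means[, i])
  M <- length(weights)
  stopifnot(length(means) == M, length(covariances) == M)
  for (S in covariances) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance matrix is not positive definite", call. = FALSE)
  }
  structure(list(weights = weights, means = means, covariances = covariances,
                 M = M, d = length(means[[1]])),
            class = "gmm_model")
}

#' @export
print.gmm_model <- function(x, ...) {
  cat(sprintf("<gmm_model> M=%d components, d=%d; weights: %s\n", x$M, x$d,
              paste(signif(x$weights, 4), collapse = ", ")))
  invisible(x)
}

# Log multivariate Gaussian density, rows of X.
log_dmvnorm <- function(X, mu, Sigma) {
  ch <- chol(Sigma)
  d <- length(mu)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

#' Mixture density of voxel feature vectors
#'
#' Evaluates the weighted sum of multivariate Gaussian component densities at
#' each row of `x`.
#'
#' @param x Numeric vector (one point) or matrix with d columns.
#' @param model A [gmm_model()].
#' @return Numeric density value(s).
#' @export
gmm_density <- function(x, model) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  dens <- numeric(nrow(X))
  for (i in seq_len(model$M)) {
    dens <- dens + model$weights[i] *
      exp(log_dmvnorm(X, model$means[[i]], model$covariances[[i]]))
  }
  dens
}

# k-means++ style selection of M initial means (deterministic given seed).
kmeanspp_init <- function(X, M, seed) {
  with_seed(seed, {
    n <- nrow(X)
    centers <- matrix(0, M, ncol(X))
    centers[1, ] <- X[sample.int(n, 1), ]
    if (M > 1) {
      d2 <- rowSums((X - rep(centers[1, ], each = n))^2)
      for (m in 2:M) {
        p <- d2 / sum(d2)
        centers[m, ] <- X[sample.int(n, 1, prob = p), ]
        d2 <- pmin(d2, rowSums((X - rep(centers[m, ], each = n))^2))
      }
    }
    centers
  })
}

regularize_cov <- function(S, cond_limit = 1e10, ridge_frac = 1e-6) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > cond_limit) {
    S <- S + diag(ridge_frac * sum(diag(S)) / nrow(S), nrow(S))
    attr(S, "regularized") <- TRUE
  }
  S
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Standard EM on d-dimensional features with full covariances. Means are
#' initialized by k-means++-style seeding under the given seed; covariances
#' start at the pooled sample covariance and weights uniform. Iterates until
#' the relative log-likelihood change drops below `tol`. The log-likelihood
#' sequence is monotone non-decreasing (up to the covariance ridge applied
#' when a component nears singularity).
#'
#' With `init = "intensity"` (two components only) the mixture is instead
#' seeded from the intensity axis: the high-uptake component starts at the
#' moments of the brightest 1.5% of voxels and the background component at
#' the moments of the rest. This deterministic start keeps EM in the basin
#' where one compact component models the striatum rather than splitting
#' the hemisphere spatially.
#'
#' @param x Numeric matrix, one feature vector per row.
#' @param M Number of components (the striatal model uses 2).
#' @param seed Initialization seed.
#' @param init Seeding scheme: `"kmeanspp"` (default) or `"intensity"`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return A [gmm_model()] with attributes `loglik` (per-iteration trace),
#'   `iterations` and `converged`.
#' @export
fit_gmm_em <- function(x, M = 2, seed = 17, init = c("kmeanspp", "intensity"),
                       tol = 1e-6, max_iter = 500) {
  init <- match.arg(init)
  X <- as.matrix(x)
  n <- nrow(X); d <- ncol(X)
  if (n <= 10 * M * d)
    stop("EM needs more than ", 10 * M * d, " feature vectors, got ", n,
         call. = FALSE)
  if (init == "intensity") {
    if (M != 2) stop("intensity seeding requires M = 2", call. = FALSE)
    hi <- X[, 1] >= stats::quantile(X[, 1], 0.985)
    if (sum(hi) < d + 2 || sum(!hi) < d + 2)
      stop("intensity seeding failed: degenerate split", call. = FALSE)
    mu <- rbind(colMeans(X[hi, , drop = FALSE]),
                colMeans(X[!hi, , drop = FALSE]))
    Sig <- list(regularize_cov(stats::cov(X[hi, , drop = FALSE]) +
                                 diag(1e-4, d)),
                regularize_cov(stats::cov(X[!hi, , drop = FALSE])))
    w <- c(mean(hi), 1 - mean(hi))
  } else {
    mu <- kmeanspp_init(X, M, seed)
    S0 <- regularize_cov(stats::cov(X))
    Sig <- replicate(M, S0, simplify = FALSE)
    w <- rep(1 / M, M)
  }
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  regularized <- FALSE
  it <- 0
  logresp <- matrix(0, n, M)
  while (it < max_iter) {
    it <- it + 1
    for (m in seq_len(M))
      logresp[, m] <- log(w[m]) + log_dmvnorm(X, mu[m, ], Sig[[m]])
    mx <- do.call(pmax, as.data.frame(logresp))
    lse <- mx + log(rowSums(exp(logresp - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    R <- exp(logresp - lse)
    nk <- colSums(R)
    w <- nk / n
    for (m in seq_len(M)) {
      mu[m, ] <- colSums(R[, m] * X) / nk[m]
      Xc <- X - rep(mu[m, ], each = n)
      S <- crossprod(Xc * sqrt(R[, m])) / nk[m]
      S <- regularize_cov(S)
      if (isTRUE(attr(S, "regularized"))) regularized <- TRUE
      Sig[[m]] <- S
    }
  }
  if (regularized)
    warning("near-singular component covariance regularized with a diagonal ridge")
  model <- gmm_model(w, lapply(seq_len(M), function(m) mu[m, ]), Sig)
  attr(model, "loglik") <- ll_trace
  attr(model, "iterations") <- it
  attr(model, "converged") <- converged
  model
}

#' Maximum-likelihood voxel labeling
#'
#' Assigns each feature vector to the component maximizing the unweighted
#' component likelihood `exp(-0.5 (x-mu)' Sigma^-1 (x-mu)) / |Sigma|^(1/2)`
#' (mixing weights and the `(2*pi)^(d/2)` constant do not enter the argmax
#' by design; set `weighted = TRUE` for posterior/MAP labeling instead).
#' Ties break toward the lower component index.
#'
#' @param x Feature matrix (rows are voxels) or a single vector.
#' @param model A fitted [gmm_model()].
#' @param weighted Include the mixing weights (MAP labeling).
#' @return Integer component labels.
#' @export
label_voxels <- function(x, model, weighted = FALSE) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  score <- matrix(0, nrow(X), model$M)
  for (m in seq_len(model$M)) {
    ch <- chol(model$covariances[[m]])
    z <- forwardsolve(t(ch), t(X) - model$means[[m]])
    score[, m] <- -0.5 * colSums(z^2) - sum(log(diag(ch))) +
      if (weighted) log(model$weights[m]) else 0
  }
  max.col(score, ties.method = "first")
}

# Index of the striatal (high-uptake) component: larger intensity-axis mean.
striatal_component <- function(model) {
  which.max(vapply(model$means, `[[`, 0, 1L))
}
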