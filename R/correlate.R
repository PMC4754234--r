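# Correlation of the shape-modulated uptake with clinical motor scores:
# Spearman rank correlation plus linear and exponential regression with
# adjusted R-squared.

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p-value from the standard
#' t approximation.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @return List with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Linear regression of a clinical score on an imaging feature
#'
#' Ordinary least squares `y = b0 + b1 x` with adjusted R-squared
#' `1 - (1 - R^2)(n - 1)/(n - 2)` and the model F-test p-value.
#'
#' @param x Feature values (e.g. SMU).
#' @param y Clinical scores.
#' @return A `regression_fit` (model `"linear"`).
#' @export
fit_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a precision warning
  r2 <- sm$r.squared
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(model = "linear",
                 coefficients = c(intercept = unname(stats::coef(fit)[1]),
                                  slope = unname(stats::coef(fit)[2])),
                 std_errors = c(intercept = sm$coefficients[1, 2],
                                slope = sm$coefficients[2, 2]),
                 r2 = r2, r2_adjusted = r2_adj, p_value = unname(p),
                 n = n, converged = TRUE, fit = fit),
            class = "regression_fit")
}

#' Exponential regression of a clinical score on an imaging feature
#'
#' Nonlinear least squares `y = a exp(b x)` on the original scale,
#' initialized from the log-linear OLS fit. Adjusted R-squared is computed on
#' the original y scale with 2 model parameters (`df = n - 2`); the model
#' p-value is the F test against the mean-only model.
#'
#' @param x Feature values.
#' @param y Clinical scores, strictly positive.
#' @return A `regression_fit` (model `"exponential"`).
#' @export
fit_exponential <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(y <= 0))
    stop("exponential model requires strictly positive scores", call. = FALSE)
  loglin <- stats::lm(log(y) ~ x)
  start <- list(a = exp(unname(stats::coef(loglin)[1])),
                b = unname(stats::coef(loglin)[2]))
  fit <- tryCatch(minpack.lm::nlsLM(y ~ a * exp(b * x), start = start,
                                    control = minpack.lm::nls.lm.control(maxiter = 200)),
                  error = function(e) NULL)
  converged <- !is.null(fit) && fit$convInfo$isConv
  if (is.null(fit)) {
    co <- unlist(start)
    pred <- co[1] * exp(co[2] * x)
    se <- c(a = NA_real_, b = NA_real_)
  } else {
    co <- stats::coef(fit)
    pred <- stats::predict(fit)
    se <- summary(fit)$coefficients[, 2]
  }
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  fstat <- ((ss_tot - ss_res) / 1) / (ss_res / (n - 2))
  p <- if (ss_res > 0 && fstat > 0)
    stats::pf(fstat, 1, n - 2, lower.tail = FALSE) else 0
  structure(list(model = "exponential",
                 coefficients = c(a = unname(co[1]), b = unname(co[2])),
                 std_errors = c(a = unname(se[1]), b = unname(se[2])),
                 r2 = r2, r2_adjusted = r2_adj, p_value = p,
                 n = n, converged = converged, fit = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> %s: %s  R2_adj=%.3f p=%.3g (n=%d)\n",
              x$model,
              paste(names(x$coefficients), signif(x$coefficients, 4),
                    sep = "=", collapse = ", "),
              x$r2_adjusted, x$p_value, x$n))
  invisible(x)
}

#' @rdname fit_linear
#' @param x A `regression_fit`.
#' @param ... Unused.
#' @export
tidy.regression_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$std_errors))
}

#' @rdname fit_linear
#' @export
glance.regression_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r.squared = x$r2,
                 adj.r.squared = x$r2_adjusted, p.value = x$p_value,
                 nobs = x$n, converged = x$converged)
}

#' Correlate shape-modulated uptake with motor severity
#'
#' Joins the per-subject feature records with the clinical table (patients
#' only) and relates SMU to the motor score: with `mode = "mean_smu"`, the
#' SMU averaged over both hemispheres against the total UPDRS-ME score; with
#' `mode = "mas"`, the SMU contralateral to the most-affected body side
#' against that side's UPDRS-ME subscore. Returns the Spearman rank
#' correlation and both regression fits.
#'
#' @param features Feature tibble ([extract_features()] rows).
#' @param clinical Clinical tibble with `subject_id`, `group`, `updrs_me`,
#'   `updrs_me_left`, `updrs_me_right`.
#' @param mode `"mean_smu"` or `"mas"`.
#' @return A `severity_correlation`: `spearman`, `linear`, `exponential`,
#'   `mode`, `n`, and the analysis table `data`.
#' @export
correlate_severity <- function(features, clinical, mode = c("mean_smu", "mas")) {
  mode <- match.arg(mode)
  df <- dplyr::inner_join(features, clinical, by = "subject_id")
  df <- df[df$group == "PD", , drop = FALSE]
  if (nrow(df) == 0) stop("no overlapping patient subjects", call. = FALSE)
  if (mode == "mean_smu") {
    x <- (df$smu_l + df$smu_r) / 2
    y <- df$updrs_me
  } else {
    mas_left <- df$updrs_me_left >= df$updrs_me_right
    # symptoms lateralize contralaterally to the damaged striatum
    x <- ifelse(mas_left, df$smu_r, df$smu_l)
    y <- ifelse(mas_left, df$updrs_me_left, df$updrs_me_right)
  }
  sp <- spearman_cor(x, y)
  structure(list(spearman = sp,
                 linear = fit_linear(x, y),
                 exponential = fit_exponential(x, y),
                 mode = mode, n = sum(is.finite(x) & is.finite(y)),
                 data = tibble::tibble(subject_id = df$subject_id,
                                       smu = x, score = y)),
            class = "severity_correlation")
}

#' @export
print.severity_correlation <- function(x, ...) {
  cat(sprintf("<severity_correlation> mode=%s n=%d  rho=%.3f (p=%.3g)\n",
              x$mode, x$n, x$spearman$rho, x$spearman$p_value))
  print(x$linear)
  print(x$exponential)
  invisible(x)
}

#' @rdname correlate_severity
#' @param x A `severity_correlation`.
#' @param ... Unused.
#' @export
glance.severity_correlation <- function(x, ...) {
  tibble::tibble(mode = x$mode, n = x$n,
                 spearman_rho = x$spearman$rho,
                 spearman_p = x$spearman$p_value,
                 linear_r2_adj = x$linear$r2_adjusted,
                 linear_p = x$linear$p_value,
                 exp_r2_adj = x$exponential$r2_adjusted,
                 exp_p = x$exponential$p_value)
}
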