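# ggplot2 displays for the main result types.

#' Plot a cohort in shape-modulated uptake space
#'
#' Scatter of right versus left SMU, coloured by group — the plane in which
#' the SVM of the composite-feature experiment separates patients from
#' controls.
#'
#' @param features Feature tibble with `smu_l`, `smu_r` and `group`.
#' @return A ggplot object.
#' @export
plot_smu_space <- function(features) {
  stopifnot(all(c("smu_l", "smu_r", "group") %in% names(features)))
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$smu_r, y = .data$smu_l,
                               colour = .data$group, shape = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "right SMU", y = "left SMU", colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_smu_space
#' @param object A `classification_report`.
#' @param ... Unused.
#' @export
autoplot.classification_report <- function(object, ...) {
  df <- object$per_subject
  df$correct <- df$group == df$predicted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decision_value, y = .data$group,
                                   colour = .data$group,
                                   shape = .data$correct)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, size = 2.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4),
                                name = "correct") +
    ggplot2::labs(x = "SVM decision value (PD-positive)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname correlate_severity
#' @param object A `severity_correlation`.
#' @param ... Unused.
#' @export
autoplot.severity_correlation <- function(object, ...) {
  df <- object$data
  xs <- seq(min(df$smu), max(df$smu), length.out = 200)
  cl <- object$linear$coefficients
  ce <- object$exponential$coefficients
  curves <- rbind(
    data.frame(smu = xs, score = cl[1] + cl[2] * xs, model = "linear"),
    data.frame(smu = xs, score = ce[1] * exp(ce[2] * xs), model = "exponential"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$smu, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(linetype = .data$model), colour = "grey30") +
    ggplot2::labs(x = if (object$mode == "mean_smu")
      "SMU (mean of both hemispheres)" else "contralateral SMU",
      y = "UPDRS motor score", linetype = NULL) +
    ggplot2::theme_minimal()
}
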