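# SVM classification of patients vs controls on the feature configurations:
# exp1 = MEU pair, exp2 = DI pair, exp3 = all four, exp4 = SMU pair,
# sbr = semi-quantitative SBR pair.

experiment_columns <- function(experiment) {
  switch(experiment,
         exp1_meu = c("meu_l", "meu_r"),
         exp2_di = c("di_l", "di_r"),
         exp3_all = c("meu_l", "meu_r", "di_l", "di_r"),
         exp4_smu = c("smu_l", "smu_r"),
         sbr = c("sbr_l", "sbr_r"),
         stop("unknown experiment: ", experiment, call. = FALSE))
}

#' Build the design matrix for a classification experiment
#'
#' Selects the feature columns of the chosen configuration and drops (with a
#' message) subjects missing any of them.
#'
#' @param records Feature tibble (one row per subject) with a `group` column
#'   (`"PD"`/`"HC"`); typically [extract_features()] output joined with the
#'   cohort table.
#' @param experiment One of `"exp1_meu"`, `"exp2_di"`, `"exp3_all"`,
#'   `"exp4_smu"`, `"sbr"`.
#' @return List: `x` (numeric matrix), `y` (factor with levels HC, PD),
#'   `subject_id`, `excluded` (dropped subject ids).
#' @export
build_design <- function(records, experiment = "exp4_smu") {
  cols <- experiment_columns(experiment)
  stopifnot(all(c(cols, "group", "subject_id") %in% names(records)))
  x <- as.matrix(records[, cols])
  ok <- stats::complete.cases(x)
  excluded <- records$subject_id[!ok]
  if (length(excluded))
    message("excluding ", length(excluded), " subject(s) with missing features: ",
            paste(excluded, collapse = ", "))
  list(x = x[ok, , drop = FALSE],
       y = factor(records$group[ok], levels = c("HC", "PD")),
       subject_id = records$subject_id[ok],
       excluded = excluded)
}

svm_decision_values <- function(x_train, y_train, x_test, kernel, cost) {
  sc <- list(center = colMeans(x_train), sd = apply(x_train, 2, stats::sd))
  sc$sd[sc$sd == 0] <- 1
  std <- function(m) sweep(sweep(m, 2, sc$center), 2, sc$sd, `/`)
  fit <- e1071::svm(std(x_train), y_train, kernel = kernel, cost = cost,
                    scale = FALSE)
  pr <- stats::predict(fit, std(x_test), decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  # orient decision values so that larger = more PD-like
  if (grepl("^HC", colnames(attr(pr, "decision.values"))[1])) dv <- -dv
  list(pred = pr, dv = dv)
}

#' Train and evaluate an SVM classifier
#'
#' Leave-one-out cross-validation by default: each subject is predicted by a
#' model trained on all others (features standardized on the training fold).
#' `cv = "none"` trains and evaluates on the full set (resubstitution).
#' Reports the correct rate, sensitivity (PD correctly flagged), specificity
#' (HC correctly flagged), all in percent, and the area under the ROC curve
#' of the decision values with PD as the positive class.
#'
#' @param design Output of [build_design()] (or a feature tibble, in which
#'   case `experiment` selects the columns).
#' @param experiment Experiment name when `design` is a tibble.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cv `"loo"` or `"none"` (resubstitution).
#' @param cost SVM cost parameter.
#' @return A `classification_report`: `correct_rate`, `auc`, `sensitivity`,
#'   `specificity`, `n_pd`, `n_hc`, `cv`, and `per_subject` tibble with
#'   predicted labels and decision values.
#' @export
evaluate_classifier <- function(design, experiment = "exp4_smu",
                                kernel = c("linear", "radial"),
                                cv = c("loo", "none"), cost = 1) {
  kernel <- match.arg(kernel)
  cv <- match.arg(cv)
  if (is.data.frame(design)) design <- build_design(design, experiment)
  x <- design$x; y <- design$y
  if (nlevels(droplevels(y)) < 2 || min(table(y)) < 2)
    stop("need at least 2 subjects per class", call. = FALSE)
  n <- nrow(x)
  if (cv == "loo") {
    pred <- factor(rep(NA_character_, n), levels = levels(y))
    dv <- numeric(n)
    for (i in seq_len(n)) {
      r <- svm_decision_values(x[-i, , drop = FALSE], y[-i],
                               x[i, , drop = FALSE], kernel, cost)
      pred[i] <- r$pred
      dv[i] <- r$dv
    }
  } else {
    r <- svm_decision_values(x, y, x, kernel, cost)
    pred <- r$pred
    dv <- r$dv
  }
  is_pd <- y == "PD"
  correct <- pred == y
  sens <- 100 * mean(correct[is_pd])
  spec <- 100 * mean(correct[!is_pd])
  rate <- 100 * mean(correct)
  auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = dv,
                                        levels = c("HC", "PD"),
                                        direction = "<", quiet = TRUE)))
  structure(list(correct_rate = rate, auc = auc,
                 sensitivity = sens, specificity = spec,
                 n_pd = sum(is_pd), n_hc = sum(!is_pd), cv = cv,
                 kernel = kernel,
                 per_subject = tibble::tibble(subject_id = design$subject_id,
                                              group = y, predicted = pred,
                                              decision_value = dv)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> %s SVM, %s\n",
                     "  correct rate %.2f%%  AUC %.4f  sensitivity %.2f%%  specificity %.2f%%",
                     "  (%d PD / %d HC)\n"),
              x$kernel, if (x$cv == "loo") "leave-one-out CV" else "resubstitution",
              x$correct_rate, x$auc, x$sensitivity, x$specificity,
              x$n_pd, x$n_hc))
  invisible(x)
}

#' @rdname evaluate_classifier
#' @param x A `classification_report`.
#' @param ... Unused.
#' @export
tidy.classification_report <- function(x, ...) x$per_subject

#' @rdname evaluate_classifier
#' @export
glance.classification_report <- function(x, ...) {
  tibble::tibble(correct_rate = x$correct_rate, auc = x$auc,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_pd = x$n_pd, n_hc = x$n_hc, cv = x$cv, kernel = x$kernel)
}
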