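# Spearman correlation, linear and exponential severity fits.

test_that("Spearman matches the hand rank formula and its limits", {
  expect_equal(spearman_cor(1:10, 1:10)$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  d <- rank(x) - rank(y)
  rho_hand <- 1 - 6 * sum(d^2) / (5 * (25 - 1))
  expect_equal(spearman_cor(x, y)$rho, rho_hand)
  expect_error(spearman_cor(rep(1, 6), 1:6), "constant")
  expect_error(spearman_cor(1:3, 3:1), "at least 4")
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- runif(30); y <- x^2 + rnorm(30, 0, 0.2)
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, base)
  expect_equal(spearman_cor(x, y^3)$rho, base)
})

test_that("linear fit recovers an exact line and keeps residuals orthogonal", {
  x <- seq(0, 3, length.out = 10)
  f <- fit_linear(x, 2 - 3 * x)
  expect_equal(unname(f$coefficients["slope"]), -3)
  expect_equal(f$r2_adjusted, 1)

  set.seed(22)
  xs <- runif(50, 0, 4); ys <- 1 + 0.5 * xs + rnorm(50)
  fn <- fit_linear(xs, ys)
  res <- ys - (fn$coefficients[1] + fn$coefficients[2] * xs)
  expect_lt(abs(sum(res * xs)), 1e-8 * sum(abs(ys)) * max(xs))
})

test_that("pure-noise linear fits centre adjusted R^2 near zero", {
  set.seed(23)
  vals <- replicate(40, fit_linear(runif(200), rnorm(200))$r2_adjusted)
  expect_lt(abs(mean(vals)), 0.02)
  expect_lt(max(abs(vals)), 0.08)
})

test_that("linear slope is recovered within 2 standard errors at n = 31", {
  set.seed(24)
  x <- runif(31, 0.5, 3)
  y <- 40 - 3 * x + rnorm(31, 0, 1)
  f <- fit_linear(x, y)
  expect_lt(abs(f$coefficients["slope"] + 3), 2 * f$std_errors["slope"])
})

test_that("exponential fit recovers exact and noisy generators", {
  x <- seq(0.2, 4, length.out = 12)
  f <- fit_exponential(x, 10 * exp(-0.5 * x))
  expect_equal(unname(f$coefficients["a"]), 10, tolerance = 1e-6)
  expect_equal(unname(f$coefficients["b"]), -0.5, tolerance = 1e-6)
  expect_equal(f$r2_adjusted, 1, tolerance = 1e-9)

  set.seed(25)
  xs <- runif(31, 0.5, 3.5)
  ys <- pmax(0.5, 40 * exp(-0.4 * xs) + rnorm(31, 0, 2))
  fn <- fit_exponential(xs, ys)
  expect_lt(abs(fn$coefficients["a"] - 40), 2 * fn$std_errors["a"])
  expect_lt(abs(fn$coefficients["b"] + 0.4), 2 * fn$std_errors["b"])
  expect_error(fit_exponential(xs, ys - 100), "positive")
})

test_that("flat exponential data never beat the mean-only model", {
  set.seed(26)
  x <- runif(40, 0, 3)
  y <- 20 + rnorm(40, 0, 2)      # b = 0 generator
  f <- fit_exponential(x, y)
  expect_lte(f$r2_adjusted, 0.05)
  expect_lt(abs(f$coefficients["b"]), 0.05)
})

test_that("severity correlation wires the contralateral rule and the link", {
  # mild-to-severe severity range: the spectrum a correlation study spans
  coh <- generate_cohort(n_pd = 31, n_hc = 8, severity_range = c(0.2, 0.9),
                         seed = 7)
  # truth-level features: exercises the statistics without the imaging chain
  feats <- tibble::tibble(
    subject_id = coh$subject_id,
    smu_l = vapply(coh$truth, function(t) t$left$smu, 0),
    smu_r = vapply(coh$truth, function(t) t$right$smu, 0))
  clin <- coh[, c("subject_id", "group", "updrs_me", "updrs_me_left",
                  "updrs_me_right")]
  res <- correlate_severity(feats, clin, mode = "mean_smu")
  expect_lt(res$spearman$rho, 0)
  expect_lt(res$spearman$p_value, 0.05)
  expect_identical(res$n, 31L)
  expect_lt(res$linear$coefficients["slope"], 0)

  # all-left-affected cohort must use the right-hemisphere SMU
  clin2 <- tibble::tibble(subject_id = feats$subject_id, group = "PD",
                          updrs_me = 30, updrs_me_left = seq_len(nrow(feats)) + 10,
                          updrs_me_right = 1)
  res2 <- correlate_severity(feats, clin2, mode = "mas")
  expect_identical(res2$data$smu, feats$smu_r)

  expect_error(correlate_severity(feats[0, ], clin, mode = "mean_smu"),
               "no overlapping")
})

test_that("shuffled pairing destroys the correlation", {
  set.seed(27)
  coh <- generate_cohort(n_pd = 31, n_hc = 8, severity_range = c(0.2, 0.9),
                         seed = 7)
  feats <- tibble::tibble(
    subject_id = coh$subject_id,
    smu_l = vapply(coh$truth, function(t) t$left$smu, 0),
    smu_r = vapply(coh$truth, function(t) t$right$smu, 0))
  clin <- coh[, c("subject_id", "group", "updrs_me", "updrs_me_left",
                  "updrs_me_right")]
  rhos <- replicate(25, {
    shuf <- clin
    pd <- shuf$group == "PD"
    shuf$updrs_me[pd] <- sample(shuf$updrs_me[pd])
    correlate_severity(feats, shuf, mode = "mean_smu")$spearman$rho
  })
  expect_lt(abs(mean(rhos)), 0.2)
})
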