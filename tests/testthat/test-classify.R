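# Design construction and SVM evaluation.

toy_records <- function(n_pd = 10, n_hc = 10, gap = 4, sd = 0.2, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("T%02d", seq_len(n_pd + n_hc)),
    group = c(rep("PD", n_pd), rep("HC", n_hc)),
    meu_l = c(rnorm(n_pd, 2, sd), rnorm(n_hc, 2 + gap / 2, sd)),
    meu_r = c(rnorm(n_pd, 2, sd), rnorm(n_hc, 2 + gap / 2, sd)),
    di_l = c(rnorm(n_pd, 0.4, 0.05), rnorm(n_hc, 0.05, 0.02)),
    di_r = c(rnorm(n_pd, 0.3, 0.05), rnorm(n_hc, 0.05, 0.02)),
    smu_l = c(rnorm(n_pd, 1, sd), rnorm(n_hc, 1 + gap, sd)),
    smu_r = c(rnorm(n_pd, 1, sd), rnorm(n_hc, 1 + gap, sd)),
    sbr_l = c(rnorm(n_pd, 1, sd), rnorm(n_hc, 2, sd)),
    sbr_r = c(rnorm(n_pd, 1, sd), rnorm(n_hc, 2, sd)))
}

test_that("each experiment selects its documented feature columns", {
  rec <- toy_records(3, 3)
  expect_identical(colnames(build_design(rec, "exp1_meu")$x), c("meu_l", "meu_r"))
  expect_identical(colnames(build_design(rec, "exp2_di")$x), c("di_l", "di_r"))
  expect_identical(colnames(build_design(rec, "exp3_all")$x),
                   c("meu_l", "meu_r", "di_l", "di_r"))
  expect_identical(colnames(build_design(rec, "exp4_smu")$x), c("smu_l", "smu_r"))
  expect_identical(colnames(build_design(rec, "sbr")$x), c("sbr_l", "sbr_r"))
  expect_identical(dim(build_design(rec, "exp4_smu")$x), c(6L, 2L))
  expect_identical(dim(build_design(rec, "exp3_all")$x), c(6L, 4L))
  expect_error(build_design(rec, "exp5"), "unknown experiment")
})

test_that("subjects with missing selected features are excluded and logged", {
  rec <- toy_records(4, 4)
  rec$meu_l[2] <- NA
  expect_message(d <- build_design(rec, "exp1_meu"), "excluding 1")
  expect_identical(d$excluded, rec$subject_id[2])
  expect_identical(nrow(d$x), 7L)
  # the missing MEU does not affect the SMU experiment
  expect_identical(nrow(build_design(rec, "exp4_smu")$x), 8L)
})

test_that("a widely separated cohort classifies perfectly under LOO", {
  rep <- evaluate_classifier(toy_records(10, 8), "exp4_smu")
  expect_equal(rep$correct_rate, 100)
  expect_equal(rep$auc, 1)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100)
  expect_identical(nrow(rep$per_subject), 18L)
})

test_that("the correct rate decomposes exactly into class rates", {
  rec <- toy_records(9, 7, gap = 1, sd = 0.8, seed = 3)  # imperfect problem
  rep <- evaluate_classifier(rec, "exp4_smu")
  expect_equal(rep$correct_rate,
               (rep$sensitivity * rep$n_pd + rep$specificity * rep$n_hc) /
                 (rep$n_pd + rep$n_hc))
})

test_that("shuffled labels carry no classification signal", {
  set.seed(44)
  rec <- toy_records(20, 20, gap = 3)
  null_runs <- replicate(60, {
    shuf <- rec
    shuf$group <- sample(shuf$group)
    r <- suppressMessages(evaluate_classifier(shuf, "exp4_smu"))
    c(r$correct_rate, r$auc)
  })
  majority <- 100 * max(table(rec$group)) / nrow(rec)
  # LOO permutation null: no skill (at or below chance; LOO is pessimistic
  # under label permutation) and uninformative decision values
  expect_lt(mean(null_runs[1, ]), majority + 3)
  expect_gt(mean(null_runs[1, ]), majority - 15)
  expect_lt(mean(null_runs[2, ]), 0.53)   # AUC: no skill (LOO null is
  expect_gt(mean(null_runs[2, ]), 0.35)   # below 0.5 on average)
})

test_that("pre-standardization column scaling changes no prediction", {
  rec <- toy_records(8, 8, gap = 1.5, sd = 0.6, seed = 5)
  base <- evaluate_classifier(rec, "exp4_smu")
  scaled <- rec
  scaled$smu_l <- scaled$smu_l * 10
  res <- evaluate_classifier(scaled, "exp4_smu")
  expect_identical(base$per_subject$predicted, res$per_subject$predicted)
  expect_equal(base$correct_rate, res$correct_rate)
})

test_that("evaluation is deterministic and rejects single-class input", {
  rec <- toy_records(6, 6, gap = 1, sd = 0.7, seed = 6)
  a <- evaluate_classifier(rec, "exp4_smu")
  b <- evaluate_classifier(rec, "exp4_smu")
  expect_identical(a$per_subject$decision_value, b$per_subject$decision_value)
  only_pd <- rec[rec$group == "PD", ]
  expect_error(evaluate_classifier(only_pd, "exp4_smu"), "2 subjects per class")
})

test_that("resubstitution mode reports at least LOO-level separation", {
  rec <- toy_records(8, 8, gap = 2, sd = 0.5, seed = 7)
  loo <- evaluate_classifier(rec, "exp4_smu", cv = "loo")
  resub <- evaluate_classifier(rec, "exp4_smu", cv = "none")
  expect_gte(resub$correct_rate + 1e-9, loo$correct_rate)
  expect_identical(resub$cv, "none")
})

test_that("duplicating every subject leaves the LOO report nearly unchanged", {
  rec <- toy_records(8, 8, gap = 2.5, sd = 0.5, seed = 8)
  dup <- rec[rep(seq_len(nrow(rec)), 2), ]
  dup$subject_id <- sprintf("D%02d", seq_len(nrow(dup)))
  r1 <- evaluate_classifier(rec, "exp4_smu")
  r2 <- evaluate_classifier(dup, "exp4_smu")
  expect_lt(abs(r1$correct_rate - r2$correct_rate), 5)
})
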