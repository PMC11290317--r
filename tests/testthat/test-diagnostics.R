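# The worked confusion tables used throughout: a published 1070-trial audit
# (main analysis), its two sensitivity reruns, and the domain-1 subgroup.
main_cc <- function() confusion_counts(tp = 37, fp = 425, tn = 562, fn = 46)
sub_cc <- function() confusion_counts(tp = 3, fp = 88, tn = 635, fn = 42)

test_that("margins: sensitivity, specificity, prevalence", {
  m <- se_sp_prevalence(main_cc())
  expect_equal(m$prevalence, 83 / 1070)
  expect_equal(m$se, 37 / 83)
  expect_equal(m$sp, 562 / 987)
  perfect <- se_sp_prevalence(confusion_counts(1, 0, 1, 0))
  expect_equal(perfect$se, 1)
  expect_equal(perfect$sp, 1)
  s <- se_sp_prevalence(sub_cc())
  expect_equal(s$se, 3 / 45)
  expect_equal(s$sp, 635 / 723)
  expect_error(se_sp_prevalence(confusion_counts(0, 3, 4, 0)),
               "positive margin")
})

test_that("literal false omission rate is FN/(FN + TN)", {
  expect_equal(for_simple(main_cc()), 46 / 608)
  expect_equal(for_simple(confusion_counts(5, 5, 7, 0)), 0)
  expect_equal(for_simple(confusion_counts(5, 5, 0, 3)), 1)
  expect_error(for_simple(confusion_counts(5, 5, 0, 0)), "FN \\+ TN")
})

test_that("adjusted FOR with rounded prevalence matches published figures", {
  expect_equal(round(100 * for_adjusted(main_cc(), prev_digits = 1), 2), 7.61)
  sens <- confusion_counts(tp = 45, fp = 487, tn = 629, fn = 49)
  expect_equal(round(100 * for_adjusted(sens, prev_digits = 1), 2), 7.26)
  age <- confusion_counts(tp = 40, fp = 438, tn = 559, fn = 41)
  expect_equal(round(100 * for_adjusted(age, prev_digits = 1), 2), 6.82)
})

test_that("with exact prevalence the two FOR estimators coincide", {
  set.seed(77)
  for (i in 1:200) {
    cc <- random_confusion()
    if (cc$fn + cc$tn == 0) next
    expect_equal(for_adjusted(cc, prev_digits = NULL), for_simple(cc),
                 tolerance = 1e-12)
  }
})

test_that("logit interval reproduces the published FOR bounds", {
  ci <- for_logit_ci(main_cc(), prev_digits = 1)
  expect_equal(round(100 * ci[["low"]], 2), 6.31)
  expect_equal(round(100 * ci[["high"]], 2), 9.14)
  age <- confusion_counts(tp = 40, fp = 438, tn = 559, fn = 41)
  ci3 <- for_logit_ci(age, prev_digits = 1)
  expect_equal(round(100 * ci3[["low"]], 2), 5.54)
  expect_equal(round(100 * ci3[["high"]], 2), 8.37)
  # interval brackets the point estimate and narrows as counts scale up
  point <- for_adjusted(main_cc(), prev_digits = 1)
  expect_lt(ci[["low"]], point)
  expect_gt(ci[["high"]], point)
  big <- confusion_counts(3700, 42500, 56200, 4600)
  ci_big <- for_logit_ci(big, prev_digits = 1)
  expect_lt(diff(ci_big), diff(ci))
  expect_lt(ci_big[["low"]], for_adjusted(big, prev_digits = 1))
  expect_gt(ci_big[["high"]], for_adjusted(big, prev_digits = 1))
  expect_error(for_logit_ci(confusion_counts(1, 0, 1, 0)), "boundary")
})

test_that("negative likelihood ratio and its log-method interval", {
  expect_equal(neg_lr(sub_cc()), (42 / 45) / (635 / 723), tolerance = 1e-12)
  # independent algebraic form: (FN (TN + FP)) / ((TP + FN) TN)
  expect_equal(neg_lr(sub_cc()), (42 * 723) / (45 * 635), tolerance = 1e-12)
  expect_equal(round(neg_lr(sub_cc()), 2), 1.06)
  ci <- neg_lr_ci(sub_cc())
  expect_equal(round(ci[["low"]], 2), 0.98)
  expect_equal(round(ci[["high"]], 2), 1.15)
  expect_lt(ci[["low"]], neg_lr(sub_cc()))
  expect_gt(ci[["high"]], neg_lr(sub_cc()))
  # scaling all counts narrows the interval around an unchanged point
  k10 <- confusion_counts(30, 880, 6350, 420)
  expect_equal(neg_lr(k10), neg_lr(sub_cc()), tolerance = 1e-12)
  expect_lt(diff(neg_lr_ci(k10)), diff(ci))
  expect_equal(neg_lr(confusion_counts(5, 3, 9, 0)), 0)
})

test_that("likelihood-ratio bands use upper-closed boundaries", {
  expect_identical(interpret_neg_lr(0.05), "highly")
  expect_identical(interpret_neg_lr(0.1), "moderately")
  expect_identical(interpret_neg_lr(0.15), "moderately")
  expect_identical(interpret_neg_lr(0.5), "somewhat")
  expect_identical(interpret_neg_lr(0.9), "rarely")
  expect_identical(interpret_neg_lr(1.0), "rarely")
  expect_identical(interpret_neg_lr(1.06), "adverse")
  expect_error(interpret_neg_lr(0), "positive")
})

test_that("diagnostic_summary assembles every statistic coherently", {
  s <- diagnostic_summary(main_cc())
  expect_s3_class(s, "diagnostic_summary")
  expect_equal(s$prevalence_used, 0.078)
  expect_equal(round(100 * s$for_adjusted, 2), 7.61)
  expect_equal(s$for_simple, 46 / 608)
  expect_identical(s$neg_lr_band, interpret_neg_lr(s$neg_lr))
  expect_lte(s$for_ci[["low"]], s$for_adjusted)
  expect_gte(s$for_ci[["high"]], s$for_adjusted)
  out <- capture.output(print(s))
  expect_true(any(grepl("7.61", out)))
  expect_true(any(grepl("differs from adjusted", out)))
  # with exact prevalence the printed note disappears
  s0 <- diagnostic_summary(main_cc(), prev_digits = NULL)
  expect_equal(s0$for_adjusted, s0$for_simple, tolerance = 1e-12)
})

test_that("logit interval attains nominal coverage under simulation", {
  # simulate confusion tables from fixed (se, sp, prevalence, n) — the
  # positive margin is fixed by design so the prevalence entering the
  # adjusted estimator is the true one — and count how often the interval
  # covers the true adjusted FOR
  se <- 0.45; sp <- 0.57; n <- 1000; npos <- 78
  prev <- npos / n
  true_for <- ((1 - se) * prev) / (sp * (1 - prev) + (1 - se) * prev)
  set.seed(2718)
  covered <- replicate(600, {
    tp <- stats::rbinom(1, npos, se)
    tn <- stats::rbinom(1, n - npos, sp)
    cc <- confusion_counts(tp, n - npos - tn, tn, npos - tp)
    ci <- tryCatch(for_logit_ci(cc, prev_digits = NULL),
                   error = function(e) return(c(NA, NA)))
    ci[[1]] <= true_for && true_for <= ci[[2]]
  })
  cov <- mean(covered, na.rm = TRUE)
  # 0.95 within ~3 Monte-Carlo SEs (3 * sqrt(.95*.05/600) ~ 0.027)
  expect_gt(cov, 0.95 - 0.03)
  expect_lt(cov, 0.95 + 0.03)
})
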