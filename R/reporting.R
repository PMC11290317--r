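#' Confusion counts from a published 1070-trial audit of RoB 2 ratings
#'
#' Reference confusion tables from a published evaluation that ran this
#' selection-bias test over 1070 randomized trials extracted from recent
#' systematic reviews and compared the results with RoB 2 ratings:
#'
#' * `main` — overall rating, mean/SD-reported trials (n = 1070);
#' * `median_added` — sensitivity analysis adding 140 median-reporting
#'   trials via the Hozo/Wan conversions (n = 1210);
#' * `age_only` — sensitivity analysis excluding the 131 trials whose
#'   baseline variable was not age (n = 1078);
#' * `domain1` — subgroup of 768 trials with an ascertainable low/high
#'   rating for RoB 2 domain 1 (randomization process).
#'
#' @return Named list of [confusion_counts()].
#' @export
reference_counts <- function() {
  list(main = confusion_counts(tp = 37, fp = 425, tn = 562, fn = 46),
       median_added = confusion_counts(tp = 45, fp = 487, tn = 629, fn = 49),
       age_only = confusion_counts(tp = 40, fp = 438, tn = 559, fn = 41),
       domain1 = confusion_counts(tp = 3, fp = 88, tn = 635, fn = 42))
}

#' Recompute the headline statistics of the reference audit
#'
#' From the four stored confusion tables of [reference_counts()] — the only
#' fixture data involved — recomputes every headline statistic: the
#' prevalence of test-positive trials, the prevalence-adjusted false
#' omission rate with its logit 95% CI for the three FOR analyses, and the
#' negative likelihood ratio with its log-method 95% CI for the domain-1
#' subgroup.
#'
#' @param prev_digits Prevalence rounding (decimals in percent) used by the
#'   adjusted FOR, default 1.
#' @param z Normal quantile for the intervals.
#' @return Data frame with columns `analysis`, `statistic`, `value`
#'   (percent scale for prevalence/FOR, ratio scale for the -LR).
#' @export
reference_diagnostics <- function(prev_digits = 1, z = 1.959964) {
  counts <- reference_counts()
  rows <- list()
  add <- function(analysis, statistic, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, statistic = statistic, value = value,
      stringsAsFactors = FALSE)
  for (nm in c("main", "median_added", "age_only")) {
    cc <- counts[[nm]]
    m <- se_sp_prevalence(cc)
    ci <- for_logit_ci(cc, prev_digits = prev_digits, z = z)
    add(nm, "prevalence_pct", 100 * m$prevalence)
    add(nm, "for_pct", 100 * for_adjusted(cc, prev_digits = prev_digits))
    add(nm, "for_ci_low_pct", 100 * ci[["low"]])
    add(nm, "for_ci_high_pct", 100 * ci[["high"]])
  }
  cc <- counts$domain1
  ci <- neg_lr_ci(cc, z = z)
  add("domain1", "neg_lr", neg_lr(cc))
  add("domain1", "neg_lr_ci_low", ci[["low"]])
  add("domain1", "neg_lr_ci_high", ci[["high"]])
  do.call(rbind, rows)
}

summary_to_list <- function(s) {
  list(counts = list(tp = s$counts$tp, fp = s$counts$fp,
                     tn = s$counts$tn, fn = s$counts$fn),
       sensitivity = s$se, specificity = s$sp,
       prevalence = s$prevalence, prevalence_used = s$prevalence_used,
       for_simple = s$for_simple, for_adjusted = s$for_adjusted,
       for_ci = as.list(s$for_ci),
       neg_lr = s$neg_lr, neg_lr_ci = as.list(s$neg_lr_ci),
       neg_lr_band = s$neg_lr_band,
       estimators_differ = abs(s$for_simple - s$for_adjusted) > 5e-5)
}

#' Render a cohort-test report
#'
#' Produces a human-readable text report and a machine-readable list
#' (serializable as JSON) for a [run_cohort()] output. Both FOR estimators
#' appear side by side, with an explicit note when prevalence rounding
#' makes them differ. Sections without data (e.g. an empty domain-1
#' subgroup) are marked "not available" rather than dropped.
#'
#' @param cohort_test A `"cohort_test"` from [run_cohort()].
#' @param prev_digits,z Passed to [diagnostic_summary()].
#' @return List with `text` (character vector of report lines) and `json`
#'   (nested list mirroring the report).
#' @export
render_report <- function(cohort_test, prev_digits = 1, z = 1.959964) {
  stopifnot(inherits(cohort_test, "cohort_test"))
  section <- function(cc) {
    ok <- tryCatch({se_sp_prevalence(cc); TRUE}, error = function(e) FALSE)
    if (!ok) return(NULL)
    summary_to_list(diagnostic_summary(cc, prev_digits = prev_digits, z = z))
  }
  overall <- section(cohort_test$confusion_overall)
  domain1 <- tryCatch(section(cohort_test$confusion_domain1),
                      error = function(e) NULL)
  json <- list(n_tested = nrow(cohort_test$results),
               n_skipped = cohort_test$n_skipped,
               n_positive = sum(cohort_test$results$test_positive),
               overall = overall,
               domain1 = domain1)
  fmt <- function(lab, s) {
    if (is.null(s)) return(sprintf("%s: not available", lab))
    c(sprintf("%s:", lab),
      sprintf("  TP %d, FP %d, TN %d, FN %d", s$counts$tp, s$counts$fp,
              s$counts$tn, s$counts$fn),
      sprintf("  FOR adjusted %.2f%% (95%% CI %.2f%%-%.2f%%); literal %.2f%%%s",
              100 * s$for_adjusted, 100 * s$for_ci$low, 100 * s$for_ci$high,
              100 * s$for_simple,
              if (s$estimators_differ) " [estimators differ: prevalence rounding]"
              else ""),
      sprintf("  -LR %.2f (95%% CI %.2f-%.2f), band: %s",
              s$neg_lr, s$neg_lr_ci$low, s$neg_lr_ci$high, s$neg_lr_band))
  }
  text <- c(sprintf("selection-bias test report: %d trials tested, %d skipped, %d positive",
                    json$n_tested, json$n_skipped, json$n_positive),
            fmt("overall RoB 2 rating (main analysis)", overall),
            fmt("RoB 2 domain 1 (subgroup analysis)", domain1))
  list(text = text, json = json)
}

#' Write a diagnostics report as JSON
#'
#' @param report Output of [render_report()], or any serializable list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- if (!is.null(report$json)) report$json else report
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
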