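#' Test a single trial for selection-bias risk
#'
#' The headline test: the trial's baseline mean difference is inserted as a
#' third study into the confirmed two-SCT fixed-effect meta-analysis and the
#' analysis is repeated. An I2 point estimate above 0% is a positive test —
#' the trial is taken to be at high risk of selection bias; I2 = 0% is
#' negative. Under true randomization the baseline variable carries no
#' heterogeneity beyond chance, so a positive reading indicates baseline
#' imbalance consistent with non-random allocation.
#'
#' @param trial A [trial_record()] (arms are normalized via
#'   [normalize_arm()]), or a list with elements `arm_a`, `arm_b` that are
#'   already [arm_summary()] objects.
#' @param pair A confirmed `"sct_pair"` from [build_confirmed_sct_pair()].
#' @param display_rounding Passed to [fixed_effect_pool()]; if `TRUE` the
#'   I2 is rounded to integer percent before the positivity call.
#' @return A list of class `"bias_test_result"`: `trial_id`, `i2`,
#'   `positive` (`i2 > 0`), `meta` (the three-study [fixed_effect_pool()]),
#'   `attempts` (SCT regenerations used by the pair).
#' @export
test_trial <- function(trial, pair, display_rounding = FALSE) {
  stopifnot(inherits(pair, "sct_pair"))
  if (inherits(trial, "trial_record")) {
    arm_a <- normalize_arm(trial$arm_a)
    arm_b <- normalize_arm(trial$arm_b)
    id <- trial$trial_id
  } else {
    arm_a <- trial$arm_a; arm_b <- trial$arm_b
    stopifnot(inherits(arm_a, "arm_summary"), inherits(arm_b, "arm_summary"))
    id <- if (!is.null(trial$trial_id)) trial$trial_id else NA_character_
  }
  effects <- list(
    mean_difference_effect(pair$sct1$arm_a, pair$sct1$arm_b),
    mean_difference_effect(pair$sct2$arm_a, pair$sct2$arm_b),
    mean_difference_effect(arm_a, arm_b))
  meta <- fixed_effect_pool(effects, display_rounding = display_rounding)
  structure(list(trial_id = id, i2 = meta$i2, positive = meta$i2 > 0,
                 meta = meta, attempts = pair$attempts),
            class = "bias_test_result")
}

#' @export
print.bias_test_result <- function(x, ...) {
  cat(sprintf("trial %s: I2 = %.2f%% -> test %s\n", x$trial_id, x$i2,
              if (x$positive) "POSITIVE (high selection-bias risk)"
              else "negative"))
  invisible(x)
}

#' Classify a test result against a RoB 2 rating
#'
#' The rating is treated as the index "diagnosis" and the I2 test as the
#' reference: TP = high-rated and test-positive, TN = low-rated and
#' test-negative, FN = low-rated and test-positive, FP = high-rated and
#' test-negative. Ratings outside the low/high dichotomy ("some_concerns",
#' "unknown") yield `NA`: such trials are skipped, not errors.
#'
#' @param rob2 Rating string.
#' @param positive Logical test result (or a `"bias_test_result"`).
#' @return One of `"TP"`, `"TN"`, `"FP"`, `"FN"`, or `NA_character_`.
#' @export
classify <- function(rob2, positive) {
  if (inherits(positive, "bias_test_result")) positive <- positive$positive
  if (!rob2 %in% c("low", "high")) return(NA_character_)
  if (rob2 == "high") {
    if (positive) "TP" else "FP"
  } else {
    if (positive) "FN" else "TN"
  }
}

#' Pick the most divergent arm pair of a multi-arm trial
#'
#' When a trial reports more than one test and/or control group, extraction
#' keeps the pair with the most significant baseline difference. Implemented
#' as the pair maximizing the two-sample z-statistic
#' `|mean_i - mean_j| / sqrt(sd_i^2/n_i + sd_j^2/n_j)`; ties go to the first
#' pair in order.
#'
#' @param arms List of [arm_summary()] objects (length `>= 2`).
#' @return Integer vector of the two selected indices.
#' @export
select_most_divergent_arms <- function(arms) {
  k <- length(arms)
  stopifnot(k >= 2L)
  best <- c(1L, 2L); best_z <- -Inf
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    z <- abs(arms[[i]]$mean - arms[[j]]$mean) /
      sqrt(arms[[i]]$sd^2 / arms[[i]]$n + arms[[j]]$sd^2 / arms[[j]]$n)
    if (z > best_z + 1e-12) {
      best <- c(i, j); best_z <- z
    }
  }
  best
}

tally_confusion <- function(classification) {
  confusion_counts(tp = sum(classification == "TP", na.rm = TRUE),
                   fp = sum(classification == "FP", na.rm = TRUE),
                   tn = sum(classification == "TN", na.rm = TRUE),
                   fn = sum(classification == "FN", na.rm = TRUE))
}

#' Run the selection-bias test over a cohort
#'
#' Tests every eligible trial in a cohort and tallies classifications
#' against both rating schemes: the overall RoB 2 rating (main analysis) and
#' the domain-1 rating restricted to low/high labels (subgroup analysis).
#'
#' Eligibility mirrors the reference workflow: the main analysis uses only
#' trials whose arms were reported as mean with SD or SE
#' (`include_converted = FALSE`); setting `include_converted = TRUE` adds
#' the median-based trials via the Hozo/Wan conversions (sensitivity
#' analysis); `variable_whitelist` restricts to named baseline variables
#' (e.g. `"age"` only).
#'
#' @param cohort A `"cohort_table"` from [read_cohort()] or
#'   [simulate_cohort()], or a list of [trial_record()]s.
#' @param cfg [sct_config()] for the comparator trials.
#' @param seed Optional integer; when given, trial `i` uses the derived seed
#'   `seed + i` (shared-pair mode uses `seed` itself), making every
#'   per-trial test independently re-runnable from the recorded seed.
#' @param shared_pair If `TRUE` one confirmed SCT pair is generated and
#'   reused for the whole cohort; default is a fresh confirmed pair per
#'   trial.
#' @param include_converted Include trials with median-based arms.
#' @param variable_whitelist Optional character vector of variable names.
#' @param display_rounding Round I2 to integer percent before thresholding.
#' @return List of class `"cohort_test"`: `results` (per-trial data frame
#'   with `trial_id`, `variable_name`, `converted`, `i2`, `test_positive`,
#'   `classification`, `classification_domain1`, `sct_seed`, `attempts`),
#'   `confusion_overall`, `confusion_domain1` (both [confusion_counts()]),
#'   `n_skipped` and `skipped_ids`.
#' @export
run_cohort <- function(cohort, cfg = sct_config(), seed = NULL,
                       shared_pair = FALSE, include_converted = FALSE,
                       variable_whitelist = NULL, display_rounding = FALSE) {
  stopifnot(length(cohort) >= 1L)
  skipped <- character(0)
  rows <- list()
  if (!is.null(seed)) seed <- as.integer(seed)

  shared <- NULL
  if (shared_pair) {
    if (!is.null(seed)) set.seed(seed)
    shared <- build_confirmed_sct_pair(cfg)
  }

  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    if (!rec$rob2_overall %in% c("low", "high")) {
      skipped <- c(skipped, rec$trial_id); next
    }
    if (!is.null(variable_whitelist) &&
        !rec$variable_name %in% variable_whitelist) {
      skipped <- c(skipped, rec$trial_id); next
    }
    arm_a <- normalize_arm(rec$arm_a)
    arm_b <- normalize_arm(rec$arm_b)
    converted <- arm_a$converted || arm_b$converted
    if (converted && !include_converted) {
      skipped <- c(skipped, rec$trial_id); next
    }
    if (shared_pair) {
      pair <- shared
      trial_seed <- if (is.null(seed)) NA_integer_ else seed
    } else {
      trial_seed <- if (is.null(seed)) NA_integer_ else seed + i
      if (!is.null(seed)) set.seed(trial_seed)
      pair <- build_confirmed_sct_pair(cfg)
    }
    res <- test_trial(list(arm_a = arm_a, arm_b = arm_b,
                           trial_id = rec$trial_id),
                      pair, display_rounding = display_rounding)
    rows[[length(rows) + 1L]] <- data.frame(
      trial_id = rec$trial_id, variable_name = rec$variable_name,
      converted = converted, i2 = res$i2, test_positive = res$positive,
      classification = classify(rec$rob2_overall, res$positive),
      classification_domain1 = classify(rec$rob2_domain1, res$positive),
      sct_seed = trial_seed, attempts = pair$attempts,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no eligible trials in cohort", call. = FALSE)
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 confusion_overall = tally_confusion(results$classification),
                 confusion_domain1 = tally_confusion(results$classification_domain1),
                 n_skipped = length(skipped), skipped_ids = skipped),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  cat(sprintf("selection-bias test over %d trials (%d skipped)\n",
              nrow(x$results), x$n_skipped))
  cat(sprintf("  positive: %d (%.1f%%)\n", sum(x$results$test_positive),
              100 * mean(x$results$test_positive)))
  cat("  vs overall rating:  "); print(x$confusion_overall)
  cat("  vs domain-1 rating: "); print(x$confusion_domain1)
  invisible(x)
}
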