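#' Configuration of the synthetic trial-cohort generator
#'
#' Simulates the kind of cohort the selection-bias test is audited on:
#' two-arm RCT baseline summaries (age-like, normally distributed subjects)
#' with a controllable fraction of trials whose arms were systematically
#' misallocated, plus RoB 2-style labels that agree with the truth up to a
#' configurable noise rate. Arm misallocation is modelled as a mean shift
#' of `delta` population SDs on one arm — the baseline-imbalance footprint
#' of non-random allocation.
#'
#' Defaults: `mu = 44`, `sigma = 21` match the first two moments of the
#' uniform(8, 80) SCT value distribution, so synthetic trials sit inside
#' the default comparator range; `biased_fraction = 0.078` mirrors a
#' realistic prevalence of test-positive trials in published cohorts.
#'
#' @param n_trials Number of trials.
#' @param mu,sigma Population mean and SD of the baseline variable.
#' @param n_per_arm_range Integer `c(min, max)` for the per-arm sample size.
#' @param delta Arm shift for biased trials, in units of `sigma` (`>= 0`).
#' @param biased_fraction Fraction of trials that are truly misallocated.
#' @param label_noise Probability that a trial's rating contradicts its
#'   true bias status.
#' @param domain1_missing Probability that the domain-1 rating is
#'   `"some_concerns"` (not ascertainable as low/high).
#' @param median_fraction Fraction of trials whose arms are reported as
#'   median-based summaries (exercises the Hozo/Wan conversion path).
#' @return An object of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_trials = 100L, mu = 44, sigma = 21,
                              n_per_arm_range = c(20L, 200L),
                              delta = 0.5, biased_fraction = 0.078,
                              label_noise = 0.1, domain1_missing = 0.28,
                              median_fraction = 0) {
  stopifnot(n_trials >= 1L, sigma > 0, delta >= 0,
            length(n_per_arm_range) == 2L,
            n_per_arm_range[1] >= 2L,
            n_per_arm_range[1] <= n_per_arm_range[2])
  for (p in c(biased_fraction, label_noise, domain1_missing, median_fraction))
    if (p < 0 || p > 1) stop("proportions must lie in [0, 1]", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials), mu = mu, sigma = sigma,
                 n_per_arm_range = as.integer(n_per_arm_range),
                 delta = delta, biased_fraction = biased_fraction,
                 label_noise = label_noise, domain1_missing = domain1_missing,
                 median_fraction = median_fraction),
            class = "cohort_sim_config")
}

rate_label <- function(truth_high, label_noise) {
  flip <- stats::runif(1) < label_noise
  if (xor(truth_high, flip)) "high" else "low"
}

summarize_raw_arm <- function(x, kind) {
  n <- length(x)
  switch(kind,
    mean_sd = raw_summary("mean_sd", mean(x), stats::sd(x), NA_real_, n),
    median_range = raw_summary("median_range", stats::median(x), min(x),
                               max(x), n),
    median_iqr = {
      q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
      raw_summary("median_iqr", stats::median(x), q[1], q[2], n)
    })
}

#' Simulate one trial record
#'
#' Draws two arms of subject-level values from `Normal(mu, sigma)`, shifts
#' arm A by `delta * sigma` when the trial is biased, summarizes each arm,
#' and attaches ratings that are truth-consistent with probability
#' `1 - label_noise`. Uses the current RNG state.
#'
#' @param cfg A [cohort_sim_config()].
#' @param biased Logical: is this trial truly misallocated?
#' @param trial_id Identifier for the record.
#' @return A [trial_record()].
#' @export
simulate_trial <- function(cfg, biased, trial_id = "T1") {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  n_a <- sample(seq.int(cfg$n_per_arm_range[1], cfg$n_per_arm_range[2]), 1L)
  n_b <- sample(seq.int(cfg$n_per_arm_range[1], cfg$n_per_arm_range[2]), 1L)
  shift <- if (biased) cfg$delta * cfg$sigma else 0
  x_a <- stats::rnorm(n_a, cfg$mu + shift, cfg$sigma)
  x_b <- stats::rnorm(n_b, cfg$mu, cfg$sigma)
  kind <- if (stats::runif(1) < cfg$median_fraction) {
    if (stats::runif(1) < 0.5) "median_range" else "median_iqr"
  } else "mean_sd"
  overall <- rate_label(biased, cfg$label_noise)
  domain1 <- if (stats::runif(1) < cfg$domain1_missing) "some_concerns"
             else rate_label(biased, cfg$label_noise)
  trial_record(trial_id, "age",
               summarize_raw_arm(x_a, kind), summarize_raw_arm(x_b, kind),
               rob2_overall = overall, rob2_domain1 = domain1)
}

#' Simulate a labelled cohort with ground truth
#'
#' Generates `cfg$n_trials` records of which `round(biased_fraction *
#' n_trials)` (randomly placed) are truly misallocated, and returns the
#' ground-truth flags separately so the pipeline under test never sees them.
#'
#' @param cfg A [cohort_sim_config()].
#' @param seed Optional integer seed for reproducible cohorts.
#' @return List with `cohort` (a `"cohort_table"`) and `truth` (data frame
#'   with `trial_id`, `biased`).
#' @export
simulate_cohort <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_biased <- round(cfg$biased_fraction * cfg$n_trials)
  biased <- rep(FALSE, cfg$n_trials)
  if (n_biased > 0) biased[sample.int(cfg$n_trials, n_biased)] <- TRUE
  ids <- sprintf("T%04d", seq_len(cfg$n_trials))
  records <- lapply(seq_len(cfg$n_trials), function(i)
    simulate_trial(cfg, biased[i], ids[i]))
  list(cohort = structure(records, class = "cohort_table"),
       truth = data.frame(trial_id = ids, biased = biased,
                          stringsAsFactors = FALSE))
}

#' Operating characteristics of the test against simulation truth
#'
#' @param results Per-trial data frame from [run_cohort()] (needs
#'   `trial_id` and `test_positive`).
#' @param truth Truth table from [simulate_cohort()].
#' @return Named list: `detection_rate` (positives among truly biased
#'   trials; `NA` when none tested), `false_positive_rate` (positives among
#'   unbiased trials), `n_biased`, `n_unbiased`.
#' @export
evaluate_against_truth <- function(results, truth) {
  stopifnot(all(results$trial_id %in% truth$trial_id))
  merged <- merge(results, truth, by = "trial_id")
  pos_b <- merged$test_positive[merged$biased]
  pos_u <- merged$test_positive[!merged$biased]
  list(detection_rate = if (length(pos_b)) mean(pos_b) else NA_real_,
       false_positive_rate = if (length(pos_u)) mean(pos_u) else NA_real_,
       n_biased = length(pos_b), n_unbiased = length(pos_u))
}
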