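# Shared fixtures and independent oracles, built in code at test time.

# A tiny valid cohort covering all four summary kinds and both ratings.
make_mixed_cohort <- function() {
  rec <- function(id, kind_a, la, s1a, s2a, na, kind_b, lb, s1b, s2b, nb,
                  overall, d1) {
    trial_record(id, "age",
                 raw_summary(kind_a, la, s1a, s2a, na),
                 raw_summary(kind_b, lb, s1b, s2b, nb),
                 rob2_overall = overall, rob2_domain1 = d1)
  }
  structure(list(
    rec("T1", "mean_sd", 65.2, 10.1, NA, 50, "mean_sd", 64.8, 9.7, NA, 52,
        "low", "low"),
    rec("T2", "mean_se", 44.0, 1.5, NA, 100, "mean_sd", 43.5, 14.2, NA, 96,
        "high", "high"),
    rec("T3", "median_iqr", 50, 40, 60, 80, "median_iqr", 49, 41, 58, 85,
        "low", "some_concerns"),
    rec("T4", "median_range", 45, 20, 78, 40, "mean_sd", 47.1, 12.0, NA, 44,
        "high", "unknown")),
    class = "cohort_table")
}

# Independent brute-force pooling oracle: plain loops, no shared code path
# with fixed_effect_pool().
naive_pool <- function(md, v) {
  w <- numeric(length(md))
  for (i in seq_along(v)) w[i] <- 1 / v[i]
  num <- 0; den <- 0
  for (i in seq_along(md)) {
    num <- num + w[i] * md[i]
    den <- den + w[i]
  }
  pooled <- num / den
  q <- 0
  for (i in seq_along(md)) q <- q + w[i] * (md[i] - pooled)^2
  df <- length(md) - 1
  i2 <- if (q == 0) 0 else 100 * max(0, (q - df) / q)
  list(pooled = pooled, se = sqrt(1 / den), q = q, df = df, i2 = i2)
}

random_confusion <- function() {
  repeat {
    x <- stats::rpois(4, lambda = sample(c(3, 20, 200), 1)) + c(1L, 1L, 1L, 0L)
    if (sum(x) >= 1 && x[1] + x[4] >= 1 && x[3] + x[2] >= 1)
      return(confusion_counts(tp = x[1], fp = x[2], tn = x[3], fn = x[4]))
  }
}
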