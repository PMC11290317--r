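test_that("arm and raw summaries enforce their invariants", {
  a <- arm_summary(65.2, 10.1, 50)
  expect_s3_class(a, "arm_summary")
  expect_false(a$converted)
  expect_error(arm_summary(65.2, 0, 50), "non-positive SD")
  expect_error(arm_summary(65.2, -1, 50), "non-positive SD")
  expect_error(arm_summary(65.2, 10, 1), ">= 2")
  expect_error(arm_summary(Inf, 10, 50))

  expect_error(raw_summary("median_range", 50, 60, 80, 30), "ordering")
  expect_error(raw_summary("median_iqr", 50, 40, 45, 30), "ordering")
  expect_error(raw_summary("median_iqr", 50, 40, NA, 30), "both spread")
  expect_error(raw_summary("banana", 1, 1, NA, 10))
})

test_that("a cohort CSV row parses into a two-arm record", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(selbias:::cohort_columns, collapse = ","),
    "T1,age,mean_sd,65.2,10.1,,50,mean_sd,64.8,9.7,,52,low,low"), tmp)
  cohort <- read_cohort(tmp)
  expect_length(cohort, 1L)
  rec <- cohort[[1]]
  expect_identical(rec$trial_id, "T1")
  expect_identical(rec$arm_a$kind, "mean_sd")
  expect_equal(rec$arm_a$location, 65.2)
  expect_equal(rec$arm_b$n, 52L)
  expect_identical(rec$rob2_overall, "low")
})

test_that("strict mode aborts on malformed rows; lenient mode skips them", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(selbias:::cohort_columns, collapse = ","),
    "T1,age,mean_sd,65.2,10.1,,50,mean_sd,64.8,9.7,,52,low,low",
    "T2,age,mean_sd,65.2,0,,50,mean_sd,64.8,9.7,,52,low,low",
    "T3,age,mean_sd,sixty,10,,50,mean_sd,64.8,9.7,,52,high,"), tmp)
  expect_error(read_cohort(tmp, strict = TRUE), "non-positive SD")
  cohort <- suppressWarnings(read_cohort(tmp, strict = FALSE))
  expect_length(cohort, 1L)
  w <- capture_warnings(read_cohort(tmp, strict = FALSE))
  expect_length(w, 2L)  # one logged skip per malformed row
  expect_match(w[1], "skipping row 2")
  expect_match(w[2], "skipping row 3")
  # blank domain-1 field becomes "unknown", preserved not coerced to low/high
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(selbias:::cohort_columns, collapse = ","),
    "T1,age,mean_sd,65.2,10.1,,50,mean_sd,64.8,9.7,,52,low,"), tmp2)
  expect_identical(read_cohort(tmp2)[[1]]$rob2_domain1, "unknown")
})

test_that("degenerate cohort files are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(selbias:::cohort_columns, collapse = ","), tmp)
  expect_error(read_cohort(tmp), "empty cohort")
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), tmp3)
  expect_error(read_cohort(tmp3), "column contract")
  tmp4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(selbias:::cohort_columns, collapse = ","),
    "T1,age,mean_sd,65.2,10.1,,50,mean_sd,64.8,9.7,,52,low,low",
    "T1,age,mean_sd,60.0,9.0,,40,mean_sd,61.0,9.5,,41,high,high"), tmp4)
  expect_error(read_cohort(tmp4), "duplicate trial_id")
})

test_that("cohort write -> read round-trips field for field", {
  cohort <- make_mixed_cohort()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, tmp)
  back <- read_cohort(tmp)
  expect_length(back, length(cohort))
  for (i in seq_along(cohort)) {
    expect_identical(back[[i]]$trial_id, cohort[[i]]$trial_id)
    expect_identical(back[[i]]$rob2_overall, cohort[[i]]$rob2_overall)
    expect_identical(back[[i]]$rob2_domain1, cohort[[i]]$rob2_domain1)
    for (arm in c("arm_a", "arm_b")) {
      expect_identical(back[[i]][[arm]]$kind, cohort[[i]][[arm]]$kind)
      expect_equal(back[[i]][[arm]]$location, cohort[[i]][[arm]]$location)
      expect_equal(back[[i]][[arm]]$spread1, cohort[[i]][[arm]]$spread1)
      expect_equal(back[[i]][[arm]]$spread2, cohort[[i]][[arm]]$spread2)
      expect_identical(back[[i]][[arm]]$n, cohort[[i]][[arm]]$n)
    }
  }
})

test_that("results CSV round-trips numerics to 12 significant digits", {
  res <- data.frame(trial_id = c("T1", "T2"),
                    i2 = c(12.345678901234, 0),
                    test_positive = c(TRUE, FALSE),
                    classification = c("FN", NA),
                    stringsAsFactors = FALSE)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_results(res, tmp)
  # NA classification serialized as empty string
  expect_true(grepl(",$", readLines(tmp)[3]))
  back <- read_results(tmp)
  expect_equal(back$i2, res$i2, tolerance = 1e-12)
  expect_identical(back$test_positive, res$test_positive)
})

test_that("validation rejects exactly the invariant-violating rows", {
  set.seed(404)
  header <- paste(selbias:::cohort_columns, collapse = ",")
  for (rep in 1:50) {
    bad <- sample(c(TRUE, FALSE), 1)
    sd1 <- if (bad) 0 else round(runif(1, 0.5, 15), 3)
    n1 <- sample(2:200, 1)
    row <- sprintf("T%d,age,mean_sd,%g,%g,,%d,mean_sd,%g,%g,,%d,%s,low",
                   rep, round(runif(1, 20, 70), 2), sd1, n1,
                   round(runif(1, 20, 70), 2), round(runif(1, 0.5, 15), 3),
                   sample(2:200, 1), sample(c("low", "high"), 1))
    tmp <- tempfile(fileext = ".csv")
    writeLines(c(header, row), tmp)
    if (bad) expect_error(read_cohort(tmp, strict = TRUE))
    else expect_length(read_cohort(tmp, strict = TRUE), 1L)
    unlink(tmp)
  }
})
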