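#' Baseline summary for one trial arm
#'
#' An `arm_summary` holds the mean, standard deviation and sample size of a
#' baseline variable (typically age, in years) for a single arm of a
#' randomized trial. This is the form the selection-bias test operates on;
#' summaries reported in other forms are brought here by [normalize_arm()].
#'
#' @param mean Arm mean of the baseline variable (finite numeric).
#' @param sd Arm standard deviation, strictly positive.
#' @param n Number of subjects in the arm, integer `>= 2`.
#' @param converted Logical flag: `TRUE` when the mean/SD pair was estimated
#'   from a median-based summary (Hozo/Wan conversion) rather than reported
#'   directly. Converted arms are excluded from the main analysis and enter
#'   only the sensitivity analysis.
#'
#' @return An object of class `"arm_summary"`: a list with elements `mean`,
#'   `sd`, `n`, `converted`.
#' @examples
#' arm_summary(65.2, 10.1, 50)
#' @export
arm_summary <- function(mean, sd, n, converted = FALSE) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("non-positive SD", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("arm sample size must be >= 2", call. = FALSE)
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd), n = n,
                 converted = isTRUE(converted)),
            class = "arm_summary")
}

#' @export
print.arm_summary <- function(x, ...) {
  cat(sprintf("arm: mean %.4g (SD %.4g), n = %d%s\n", x$mean, x$sd, x$n,
              if (x$converted) " [converted]" else ""))
  invisible(x)
}

#' Raw (as-reported) arm summary
#'
#' Trials report baseline variables in one of four shapes; `raw_summary`
#' captures the reported numbers verbatim so that conversion to mean/SD is an
#' explicit, testable step.
#'
#' @param kind One of `"mean_sd"`, `"mean_se"`, `"median_range"`
#'   (median with min--max) or `"median_iqr"` (median with first and third
#'   quartile).
#' @param location The mean (for `mean_*` kinds) or the median.
#' @param spread1 SD, SE, minimum, or first quartile, depending on `kind`.
#' @param spread2 Maximum or third quartile; `NA` for `mean_*` kinds.
#' @param n Arm sample size, integer `>= 2`.
#'
#' @return An object of class `"raw_summary"`.
#' @seealso [normalize_arm()] for the dispatch to mean/SD form.
#' @export
raw_summary <- function(kind, location, spread1, spread2 = NA_real_, n) {
  kind <- match.arg(kind, c("mean_sd", "mean_se", "median_range", "median_iqr"))
  stopifnot(is.numeric(location), length(location) == 1L, is.finite(location),
            is.numeric(spread1), length(spread1) == 1L, is.finite(spread1))
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("arm sample size must be >= 2", call. = FALSE)
  spread2 <- as.numeric(spread2)
  if (kind == "mean_sd" && spread1 <= 0)
    stop("non-positive SD", call. = FALSE)
  if (kind == "mean_se" && spread1 <= 0)
    stop("non-positive SE", call. = FALSE)
  if (kind %in% c("median_range", "median_iqr")) {
    if (is.na(spread2))
      stop(sprintf("'%s' requires both spread values", kind), call. = FALSE)
    if (spread1 > location || location > spread2)
      stop("ordering violation: need spread1 <= median <= spread2", call. = FALSE)
  }
  structure(list(kind = kind, location = as.numeric(location),
                 spread1 = as.numeric(spread1), spread2 = spread2, n = n),
            class = "raw_summary")
}

#' One trial's extracted record
#'
#' Bundles the two arm summaries of the single baseline variable extracted
#' from a trial with its RoB 2 ratings (the Cochrane Risk of Bias tool,
#' version 2): the overall rating and the domain-1 rating ("bias arising from
#' the randomization process"). Ratings of `"some_concerns"` or `"unknown"`
#' are preserved; trials carrying them are skipped (not errors) where a
#' low/high dichotomy is required.
#'
#' @param trial_id Identifier, unique within a cohort.
#' @param variable_name Name of the baseline variable, e.g. `"age"`.
#' @param arm_a,arm_b [raw_summary()] objects for the two arms.
#' @param rob2_overall `"low"` or `"high"` (`"some_concerns"` is accepted
#'   and preserved; such trials are outside the low/high study design and
#'   are skipped, with a logged count, by [run_cohort()]).
#' @param rob2_domain1 `"low"`, `"high"`, `"some_concerns"` or `"unknown"`.
#' @return An object of class `"trial_record"`.
#' @export
trial_record <- function(trial_id, variable_name, arm_a, arm_b,
                         rob2_overall, rob2_domain1 = "unknown") {
  stopifnot(is.character(trial_id), nzchar(trial_id),
            inherits(arm_a, "raw_summary"), inherits(arm_b, "raw_summary"))
  rob2_overall <- match.arg(rob2_overall, c("low", "high", "some_concerns"))
  rob2_domain1 <- match.arg(rob2_domain1,
                            c("low", "high", "some_concerns", "unknown"))
  structure(list(trial_id = trial_id, variable_name = variable_name,
                 arm_a = arm_a, arm_b = arm_b,
                 rob2_overall = rob2_overall, rob2_domain1 = rob2_domain1),
            class = "trial_record")
}

# Fixed column contract for cohort CSV files; one row = one trial.
cohort_columns <- c("trial_id", "variable_name",
                    "kind_a", "loc_a", "spread1_a", "spread2_a", "n_a",
                    "kind_b", "loc_b", "spread1_b", "spread2_b", "n_b",
                    "rob2_overall", "rob2_domain1")

row_to_record <- function(row) {
  arm_a <- raw_summary(row$kind_a, row$loc_a, row$spread1_a, row$spread2_a,
                       row$n_a)
  arm_b <- raw_summary(row$kind_b, row$loc_b, row$spread1_b, row$spread2_b,
                       row$n_b)
  d1 <- row$rob2_domain1
  if (is.na(d1) || !nzchar(d1)) d1 <- "unknown"
  trial_record(row$trial_id, row$variable_name, arm_a, arm_b,
               row$rob2_overall, d1)
}

#' Read a cohort table from CSV
#'
#' Reads and validates a cohort of trial records. The file must carry the
#' fixed header `trial_id, variable_name, kind_a, loc_a, spread1_a,
#' spread2_a, n_a, kind_b, loc_b, spread1_b, spread2_b, n_b, rob2_overall,
#' rob2_domain1`. Missing values are empty strings; decimal separator is the
#' point. Each row is validated against the arm-summary invariants (n >= 2,
#' positive SD for `mean_sd` rows, ordered median summaries).
#'
#' @param path Path to a CSV file.
#' @param strict If `TRUE` (default) any malformed row aborts the read with
#'   an informative error; if `FALSE`, malformed rows are dropped and each
#'   skip is reported via a warning.
#' @return An object of class `"cohort_table"`: a list of [trial_record()]
#'   objects with unique ids.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), cohort_columns))
    stop("cohort header does not match the documented column contract",
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty cohort", call. = FALSE)
  num_cols <- c("loc_a", "spread1_a", "spread2_a", "n_a",
                "loc_b", "spread1_b", "spread2_b", "n_b")
  records <- vector("list", nrow(df))
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    for (cc in num_cols) {
      v <- row[[cc]]
      if (is.na(v) || !nzchar(v)) {
        row[[cc]] <- NA_real_
      } else {
        x <- suppressWarnings(as.numeric(v))
        # NaN (not NA) marks a non-numeric token so validation rejects it
        row[[cc]] <- if (is.na(x)) NaN else x
      }
    }
    rec <- tryCatch(row_to_record(as.list(row)), error = function(e) e)
    if (inherits(rec, "error")) {
      msg <- sprintf("row %d (%s): %s", i, row$trial_id, conditionMessage(rec))
      if (strict) stop(msg, call. = FALSE)
      warning("skipping ", msg, call. = FALSE)
    } else {
      records[[i]] <- rec
      keep[i] <- TRUE
    }
  }
  records <- records[keep]
  if (length(records) == 0L) stop("empty cohort", call. = FALSE)
  ids <- vapply(records, `[[`, "", "trial_id")
  if (anyDuplicated(ids))
    stop("duplicate trial_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  structure(records, class = "cohort_table")
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: emits the fixed column contract, with `NA`
#' fields as empty strings. `read_cohort(write_cohort(x))` reproduces `x`
#' field for field.
#'
#' @param cohort A `"cohort_table"` or a list of [trial_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- do.call(rbind, lapply(cohort, function(r) {
    data.frame(trial_id = r$trial_id, variable_name = r$variable_name,
               kind_a = r$arm_a$kind, loc_a = r$arm_a$location,
               spread1_a = r$arm_a$spread1, spread2_a = r$arm_a$spread2,
               n_a = r$arm_a$n,
               kind_b = r$arm_b$kind, loc_b = r$arm_b$location,
               spread1_b = r$arm_b$spread1, spread2_b = r$arm_b$spread2,
               n_b = r$arm_b$n,
               rob2_overall = r$rob2_overall, rob2_domain1 = r$rob2_domain1,
               stringsAsFactors = FALSE)
  }))
  write_table_full_precision(df, path)
  invisible(path)
}

# CSV writer preserving >= 12 significant digits on round-trip.
write_table_full_precision <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- vapply(x, function(v) sprintf("%.15g", v), "")
    out[is.na(x)] <- ""
    out
  })
  df[!num] <- lapply(df[!num], function(x) ifelse(is.na(x), "", as.character(x)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write per-trial test results
#'
#' Serializes the per-trial output of [run_cohort()] (trial id, I2, test
#' positivity, classification, seed, attempts) as CSV. Numeric fields
#' round-trip to at least 12 significant digits; `NA` classifications (for
#' trials outside the low/high dichotomy) are written as empty strings.
#'
#' @param results Data frame of per-trial results, as in the `results`
#'   element of [run_cohort()] output.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) >= 1L)
  write_table_full_precision(results, path)
  invisible(path)
}

#' Read back a per-trial results CSV written by [write_results()]
#' @param path CSV path.
#' @return Data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("test_positive" %in% names(df))
    df$test_positive <- as.logical(df$test_positive)
  df
}
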