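#' Convert a standard error to a standard deviation
#'
#' `SD = SE * sqrt(N)`, the usual back-conversion when a trial reports the
#' standard error of the arm mean instead of the SD.
#'
#' @param se Standard error of the mean, strictly positive.
#' @param n Arm sample size, integer `>= 2`.
#' @return The standard deviation.
#' @examples
#' se_to_sd(2, 25)   # 10
#' @export
se_to_sd <- function(se, n) {
  if (!is.numeric(se) || length(se) != 1L || !is.finite(se) || se <= 0)
    stop("non-positive SE", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  se * sqrt(n)
}

# Sample-size thresholds of the Hozo range-based SD estimator.
hozo_small_n <- 15L
hozo_medium_n <- 70L

#' Estimate mean and SD from a median with min-max range (Hozo)
#'
#' Hozo-style estimators for a sample summarized as minimum `a`, median `m`,
#' maximum `b` and size `n`:
#' mean = `(a + 2m + b)/4`; SD by sample-size branch:
#' `sqrt((1/12) * ((a - 2m + b)^2 / 4 + (b - a)^2))` for `n <= 15`,
#' `(b - a)/4` for `15 < n <= 70`, and `(b - a)/6` for `n > 70`.
#'
#' @param a Minimum; `m` median; `b` maximum (must satisfy `a <= m <= b`).
#' @param m,b See `a`.
#' @param n Sample size, integer `>= 2`.
#' @return Named list with `mean` and `sd`.
#' @examples
#' hozo_mean_sd(20, 50, 80, n = 100)  # sd = (80 - 20)/6 = 10
#' @export
hozo_mean_sd <- function(a, m, b, n) {
  stopifnot(is.numeric(a), is.numeric(m), is.numeric(b),
            is.finite(a), is.finite(m), is.finite(b))
  if (a > m || m > b)
    stop("ordering violation: need a <= m <= b", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  mn <- (a + 2 * m + b) / 4
  sd <- if (n <= hozo_small_n) {
    sqrt(((a - 2 * m + b)^2 / 4 + (b - a)^2) / 12)
  } else if (n <= hozo_medium_n) {
    (b - a) / 4
  } else {
    (b - a) / 6
  }
  if (sd <= 0) stop("degenerate range yields non-positive SD", call. = FALSE)
  list(mean = mn, sd = sd)
}

#' Estimate mean and SD from a median with IQR (Wan)
#'
#' Wan-style estimators for a sample summarized as first quartile `q1`,
#' median `m`, third quartile `q3` and size `n`:
#' mean = `(q1 + m + q3)/3`;
#' SD = `(q3 - q1) / (2 * qnorm((0.75 n - 0.125)/(n + 0.25)))`.
#' As `n` grows the denominator tends to `2 * qnorm(0.75) ~ 1.349`, the
#' familiar IQR/1.349 rule for normal samples.
#'
#' @param q1,m,q3 Quartile summary, `q1 <= m <= q3` with `q1 < q3`.
#' @param n Sample size, integer `>= 2`.
#' @return Named list with `mean` and `sd`.
#' @export
wan_mean_sd <- function(q1, m, q3, n) {
  stopifnot(is.numeric(q1), is.numeric(m), is.numeric(q3),
            is.finite(q1), is.finite(m), is.finite(q3))
  if (q1 > m || m > q3)
    stop("ordering violation: need q1 <= m <= q3", call. = FALSE)
  if (q1 == q3) stop("degenerate IQR (q1 == q3) yields SD = 0", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2", call. = FALSE)
  eta <- stats::qnorm((0.75 * n - 0.125) / (n + 0.25))
  list(mean = (q1 + m + q3) / 3, sd = (q3 - q1) / (2 * eta))
}

#' Normalize a reported summary to mean/SD form
#'
#' Dispatches on the summary kind: `mean_sd` passes through, `mean_se`
#' applies [se_to_sd()], `median_range` applies [hozo_mean_sd()] and
#' `median_iqr` applies [wan_mean_sd()]. The returned [arm_summary()] carries
#' a `converted` flag that is `TRUE` only for the median-based kinds:
#' SE-reported arms belong to the main analysis (only trials lacking a mean
#' with SD or SE are deferred to the sensitivity analysis).
#'
#' @param raw A [raw_summary()].
#' @return An [arm_summary()].
#' @export
normalize_arm <- function(raw) {
  stopifnot(inherits(raw, "raw_summary"))
  switch(raw$kind,
    mean_sd = arm_summary(raw$location, raw$spread1, raw$n, converted = FALSE),
    mean_se = arm_summary(raw$location, se_to_sd(raw$spread1, raw$n), raw$n,
                          converted = FALSE),
    median_range = {
      est <- hozo_mean_sd(raw$spread1, raw$location, raw$spread2, raw$n)
      arm_summary(est$mean, est$sd, raw$n, converted = TRUE)
    },
    median_iqr = {
      est <- wan_mean_sd(raw$spread1, raw$location, raw$spread2, raw$n)
      arm_summary(est$mean, est$sd, raw$n, converted = TRUE)
    })
}
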