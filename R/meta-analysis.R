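#' Mean-difference effect of a two-arm comparison
#'
#' Raw mean difference with the standard two-sample variance,
#' `md = mean_a - mean_b`, `var = sd_a^2/n_a + sd_b^2/n_b` — the
#' "Mean Difference, IV, Fixed" effect measure of standard meta-analysis
#' software.
#'
#' @param arm_a,arm_b [arm_summary()] objects.
#' @return A list of class `"study_effect"` with elements `md` and `var`.
#' @export
mean_difference_effect <- function(arm_a, arm_b) {
  stopifnot(inherits(arm_a, "arm_summary"), inherits(arm_b, "arm_summary"))
  v <- arm_a$sd^2 / arm_a$n + arm_b$sd^2 / arm_b$n
  if (!is.finite(v) || v <= 0)
    stop("effect variance must be positive and finite", call. = FALSE)
  structure(list(md = arm_a$mean - arm_b$mean, var = v),
            class = "study_effect")
}

#' The I2 heterogeneity point estimate
#'
#' `I2 = 100 * max(0, (Q - df)/Q)` percent, defined as 0 when `Q = 0`.
#' The selection-bias test reads this value off a three-study baseline
#' meta-analysis: any strictly positive I2 is a positive test.
#'
#' @param q Cochran's Q statistic, `>= 0`.
#' @param df Degrees of freedom (number of studies minus one), `>= 1`.
#' @return I2 in percent, a value in `[0, 100)`.
#' @export
i_squared <- function(q, df) {
  stopifnot(is.numeric(q), length(q) == 1L, is.numeric(df), df >= 1)
  if (!is.finite(q) || q < 0) stop("Q must be non-negative", call. = FALSE)
  if (q == 0) return(0)
  100 * max(0, (q - df) / q)
}

#' Fixed-effect inverse-variance pooling with Cochran's Q and I2
#'
#' Pools study effects with weights `w_i = 1/var_i`:
#' pooled estimate `sum(w * md)/sum(w)`, standard error `sqrt(1/sum(w))`,
#' heterogeneity `Q = sum(w * (md - pooled)^2)` on `k - 1` degrees of
#' freedom, and the I2 point estimate from [i_squared()].
#'
#' @param effects List of `"study_effect"` objects (at least two), or a
#'   list of lists each carrying `md` and `var`.
#' @param display_rounding If `TRUE`, round I2 to integer percent as
#'   meta-analysis software displays it. The default keeps the unrounded
#'   value, so that "I2 > 0" means `Q > df` strictly; rounding first would
#'   send values in `(0, 0.5)` to zero and change borderline test calls.
#' @return An object of class `"meta_result"`: list with `pooled_md`,
#'   `pooled_se`, `q`, `df`, `i2`, `k`.
#' @examples
#' e <- list(list(md = 0, var = 1), list(md = 0, var = 1), list(md = 3, var = 1))
#' fixed_effect_pool(e)  # q = 6, i2 = 66.67
#' @export
fixed_effect_pool <- function(effects, display_rounding = FALSE) {
  k <- length(effects)
  if (k < 2L) stop("need at least 2 studies to pool", call. = FALSE)
  md <- vapply(effects, function(e) as.numeric(e$md), 0)
  v <- vapply(effects, function(e) as.numeric(e$var), 0)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all effect variances must be positive and finite", call. = FALSE)
  w <- 1 / v
  pooled <- sum(w * md) / sum(w)
  q <- sum(w * (md - pooled)^2)
  df <- k - 1L
  i2 <- i_squared(q, df)
  if (display_rounding) i2 <- round(i2)
  structure(list(pooled_md = pooled, pooled_se = sqrt(1 / sum(w)),
                 q = q, df = df, i2 = i2, k = k),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effect meta-analysis of %d studies\n", x$k))
  cat(sprintf("  pooled MD: %.4f (SE %.4f)\n", x$pooled_md, x$pooled_se))
  cat(sprintf("  Q = %.4f on %d df;  I2 = %.2f%%\n", x$q, x$df, x$i2))
  invisible(x)
}
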