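#' Confusion counts of test results against bias ratings
#'
#' An all-zero table is representable (e.g. an empty subgroup tally), but
#' every diagnostic statistic requires its margins to be non-empty and
#' errors otherwise.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `"confusion_counts"`.
#' @examples
#' confusion_counts(tp = 37, fp = 425, tn = 562, fn = 46)
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], tn = counts[3],
                 fn = counts[4]), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d, FP %d, TN %d, FN %d (total %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Sensitivity, specificity and prevalence of a confusion table
#'
#' `se = TP/(TP+FN)`, `sp = TN/(TN+FP)`, `prevalence = (TP+FN)/total`.
#' Here "condition positive" means test-positive for selection-bias risk
#' (I2 > 0%) and the rating plays the role of the index test.
#'
#' @param c A [confusion_counts()].
#' @return Named list `se`, `sp`, `prevalence`.
#' @export
se_sp_prevalence <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn < 1L) stop("empty positive margin (TP + FN = 0)", call. = FALSE)
  if (c$tn + c$fp < 1L) stop("empty negative margin (TN + FP = 0)", call. = FALSE)
  total <- c$tp + c$fp + c$tn + c$fn
  list(se = c$tp / (c$tp + c$fn), sp = c$tn / (c$tn + c$fp),
       prevalence = (c$tp + c$fn) / total)
}

#' False omission rate, literal form
#'
#' The direct ratio `FN / (FN + TN)`: among trials the rating calls
#' negative (low bias), the fraction that are actually test-positive.
#'
#' @param c A [confusion_counts()].
#' @return A proportion in `[0, 1]`.
#' @export
for_simple <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$fn + c$tn < 1L) stop("FN + TN = 0", call. = FALSE)
  c$fn / (c$fn + c$tn)
}

round_prevalence <- function(prevalence, prev_digits) {
  if (is.null(prev_digits)) return(prevalence)
  round(100 * prevalence, prev_digits) / 100
}

#' False omission rate, prevalence-adjusted predictive-value form
#'
#' `FOR = (1 - se) p / (sp (1 - p) + (1 - se) p)`, where `p` is the
#' prevalence of test-positive trials. With the exact prevalence this is
#' algebraically identical to [for_simple()]; the practical difference is
#' that diagnostic calculators take `p` as a separately entered, typically
#' pre-rounded figure. With `prev_digits = 1` (default) the prevalence is
#' rounded to one decimal in percent before use, which is the convention
#' that reproduces published FOR figures computed that way; pass
#' `prev_digits = NULL` for the exact-prevalence (literal) value.
#'
#' @param c A [confusion_counts()].
#' @param prev_digits Decimal places of the prevalence in percent, or
#'   `NULL` for no rounding.
#' @return A proportion in `[0, 1]`.
#' @examples
#' cc <- confusion_counts(tp = 37, fp = 425, tn = 562, fn = 46)
#' for_adjusted(cc)                      # 0.0761 (prevalence taken as 7.8%)
#' for_adjusted(cc, prev_digits = NULL)  # identical to for_simple(cc)
#' @export
for_adjusted <- function(c, prev_digits = 1) {
  m <- se_sp_prevalence(c)
  p <- round_prevalence(m$prevalence, prev_digits)
  num <- (1 - m$se) * p
  den <- m$sp * (1 - p) + num
  if (den <= 0) stop("degenerate denominator", call. = FALSE)
  num / den
}

#' Logit (delta-method) confidence interval for the false omission rate
#'
#' Builds the standard logit-scale interval for the negative predictive
#' value `NPV = 1 - FOR` with
#' `var(logit NPV) = (1 - sp)/(sp (TN + FP)) + se/((1 - se)(TP + FN))`,
#' back-transforms `logit(NPV) -+ z sqrt(var)` through the logistic, and
#' maps the bounds to the FOR scale (`1 - NPV`, order swapped). The point
#' estimate is [for_adjusted()] with the same prevalence rounding.
#'
#' @param c A [confusion_counts()].
#' @param prev_digits Prevalence rounding, as in [for_adjusted()].
#' @param z Normal quantile, default `1.959964` (95% coverage).
#' @return Named numeric `c(low, high)` on the proportion scale.
#' @export
for_logit_ci <- function(c, prev_digits = 1, z = 1.959964) {
  m <- se_sp_prevalence(c)
  if (m$se <= 0 || m$se >= 1 || m$sp <= 0 || m$sp >= 1)
    stop("logit interval undefined at boundary sensitivity/specificity",
         call. = FALSE)
  npv <- 1 - for_adjusted(c, prev_digits = prev_digits)
  v <- (1 - m$sp) / (m$sp * (c$tn + c$fp)) +
    m$se / ((1 - m$se) * (c$tp + c$fn))
  npv_lo <- stats::plogis(stats::qlogis(npv) - z * sqrt(v))
  npv_hi <- stats::plogis(stats::qlogis(npv) + z * sqrt(v))
  c(low = 1 - npv_hi, high = 1 - npv_lo)
}

#' Negative likelihood ratio
#'
#' `-LR = (1 - se)/sp`: how much a negative (low-bias) rating changes the
#' odds of the condition. Values below 1 mean a low-bias rating argues
#' against high selection-bias risk; values above 1 mean the rating makes
#' high risk *more* likely.
#'
#' @param c A [confusion_counts()].
#' @return A positive real.
#' @export
neg_lr <- function(c) {
  m <- se_sp_prevalence(c)
  if (m$sp <= 0) stop("specificity is zero", call. = FALSE)
  (1 - m$se) / m$sp
}

#' Log-method confidence interval for the negative likelihood ratio
#'
#' `var(ln -LR) = se/((1 - se)(TP + FN)) + (1 - sp)/(sp (TN + FP))`;
#' interval `exp(ln(-LR) -+ z sqrt(var))`.
#'
#' @param c A [confusion_counts()].
#' @param z Normal quantile, default `1.959964`.
#' @return Named numeric `c(low, high)`.
#' @export
neg_lr_ci <- function(c, z = 1.959964) {
  m <- se_sp_prevalence(c)
  if (m$se <= 0 || m$se >= 1 || m$sp <= 0 || m$sp >= 1)
    stop("log interval undefined at boundary sensitivity/specificity",
         call. = FALSE)
  lr <- neg_lr(c)
  v <- m$se / ((1 - m$se) * (c$tp + c$fn)) +
    (1 - m$sp) / (m$sp * (c$tn + c$fp))
  c(low = exp(log(lr) - z * sqrt(v)), high = exp(log(lr) + z * sqrt(v)))
}

#' Interpret a negative likelihood ratio
#'
#' Conventional bands for how likely a low-bias rating makes the *absence*
#' of the condition: `< 0.1` highly likely, `(0.1, 0.2]` moderately,
#' `(0.2, 0.5]` somewhat, `(0.5, 1.0]` rarely likely; values above 1 are
#' labelled `"adverse"` — the rating points the wrong way. Shared endpoints
#' are resolved upper-closed (so 0.5 is "somewhat").
#'
#' @param value Positive real.
#' @return One of `"highly"`, `"moderately"`, `"somewhat"`, `"rarely"`,
#'   `"adverse"`.
#' @export
interpret_neg_lr <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0)
    stop("-LR must be a positive number", call. = FALSE)
  if (value < 0.1) "highly"
  else if (value <= 0.2) "moderately"
  else if (value <= 0.5) "somewhat"
  else if (value <= 1.0) "rarely"
  else "adverse"
}

#' Full diagnostic-accuracy summary of a confusion table
#'
#' Computes sensitivity, specificity, prevalence, both false-omission-rate
#' estimators with the logit 95% CI, and the negative likelihood ratio with
#' its log-method 95% CI and interpretation band. The two FOR estimators
#' are reported side by side: when prevalence rounding makes them differ,
#' the printed report says so explicitly rather than hiding the choice.
#'
#' @param c A [confusion_counts()].
#' @param prev_digits Prevalence rounding for the adjusted FOR (default 1
#'   decimal in percent); `NULL` disables rounding, collapsing the two
#'   estimators.
#' @param z Normal quantile for both intervals.
#' @return Object of class `"diagnostic_summary"`.
#' @examples
#' diagnostic_summary(confusion_counts(tp = 37, fp = 425, tn = 562, fn = 46))
#' @export
diagnostic_summary <- function(c, prev_digits = 1, z = 1.959964) {
  m <- se_sp_prevalence(c)
  boundary <- m$se <= 0 || m$se >= 1 || m$sp <= 0 || m$sp >= 1
  structure(list(
    counts = c,
    se = m$se, sp = m$sp, prevalence = m$prevalence,
    prevalence_used = round_prevalence(m$prevalence, prev_digits),
    for_simple = for_simple(c),
    for_adjusted = for_adjusted(c, prev_digits = prev_digits),
    for_ci = if (boundary) c(low = NA_real_, high = NA_real_)
             else for_logit_ci(c, prev_digits = prev_digits, z = z),
    neg_lr = if (m$sp > 0) neg_lr(c) else NA_real_,
    neg_lr_ci = if (boundary) c(low = NA_real_, high = NA_real_)
                else neg_lr_ci(c, z = z),
    neg_lr_band = if (m$sp > 0 && neg_lr(c) > 0) interpret_neg_lr(neg_lr(c))
                  else NA_character_,
    prev_digits = prev_digits, z = z), class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  pct <- function(p) sprintf("%.2f%%", 100 * p)
  cat("diagnostic accuracy of the bias-risk rating vs the I2 test\n")
  cat("  "); print(x$counts)
  cat(sprintf("  sensitivity %s, specificity %s, prevalence %s (used as %s)\n",
              pct(x$se), pct(x$sp), pct(x$prevalence), pct(x$prevalence_used)))
  cat(sprintf("  FOR (adjusted): %s (95%% CI %s-%s)\n", pct(x$for_adjusted),
              pct(x$for_ci[["low"]]), pct(x$for_ci[["high"]])))
  cat(sprintf("  FOR (literal FN/(FN+TN)): %s%s\n", pct(x$for_simple),
              if (abs(x$for_simple - x$for_adjusted) > 5e-5)
                "  [differs from adjusted: prevalence rounding]" else ""))
  cat(sprintf("  -LR: %.2f (95%% CI %.2f-%.2f) -> %s\n", x$neg_lr,
              x$neg_lr_ci[["low"]], x$neg_lr_ci[["high"]], x$neg_lr_band))
  invisible(x)
}
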