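---
title: "Testing single randomized trials for selection-bias risk with baseline I2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing single randomized trials for selection-bias risk with baseline I2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selbias)
```

## The idea behind the test

A correctly randomized trial balances baseline characteristics between its
arms up to the play of chance. Consequently, if baseline summaries (say,
mean age per arm) from several randomized studies are pooled in a
fixed-effect meta-analysis, the between-study heterogeneity of the baseline
mean difference should be zero: baseline variables do not share the causes
of heterogeneity that outcome variables have, so any heterogeneity beyond
chance points at a failure of random allocation — selection bias.

`selbias` turns this observation into a test for a *single* trial. Two
"simulated comparator trials" (SCTs) are constructed so that they are
homogeneous by design and pool to an I2 point estimate of exactly 0%. The
tested trial's baseline mean difference is then inserted as a third study
and the fixed-effect inverse-variance meta-analysis is repeated:

* I2 = 0%: negative test — no indication of selection-bias risk;
* I2 > 0%: positive test — the trial's baseline imbalance exceeds what the
  homogeneous anchor tolerates, and the trial is flagged as being at high
  risk of selection bias.

All pooling machinery is the standard fixed-effect apparatus: weights
$w_i = 1/v_i$, pooled effect $\hat\mu = \sum w_i y_i / \sum w_i$, Cochran's
$Q = \sum w_i (y_i - \hat\mu)^2$ on $k - 1$ degrees of freedom, and
$I^2 = 100\% \cdot \max(0, (Q - df)/Q)$. The effect measure is the raw mean
difference with variance $s_a^2/n_a + s_b^2/n_b$.

### The positivity rule

The test hinges on "I2 > 0%". We apply the rule to the *unrounded* I2, so a
positive test means $Q > df$ strictly. Meta-analysis software rounds the
displayed I2 to whole percent, which would silently send values in
$(0, 0.5)$ to zero; `display_rounding = TRUE` in `fixed_effect_pool()` and
`run_cohort()` reproduces that display convention when compatibility with
software read-outs matters. The default is the unrounded rule, which is the
faithful reading of the positivity threshold.

## How an SCT is built

An SCT mimics a two-arm trial whose allocation is random by construction:

1. draw `count = 200` integers uniformly with replacement from
   `[lower, upper] = [8, 80]` (an age-like range in years) and sort them
   ascending;
2. generate a permuted-block allocation sequence over A/B with block size
   4 — every block of four labels contains two A and two B in random order;
3. pair the i-th sorted value with the i-th label, giving 100 subjects per
   arm, and summarize each arm by its mean and sample SD (n − 1).

Sorting before allocation is the crucial step: within any block of four,
the values are consecutive order statistics of the 200 draws, so the A and
B sums inside a block can differ only by within-block spacings. The arm
mean difference is therefore tiny (empirically, its SD is about 0.09 years
against arm SDs near 21), while the inverse-variance weighting assumes the
much larger nominal variance $s^2(1/100 + 1/100) \approx 8.7$. Two such
SCTs consequently pool to $Q \approx 10^{-3} \ll 1 = df$, i.e. I2 = 0, on
essentially every draw. `build_confirmed_sct_pair()` still verifies the
zero I2 explicitly and regenerates the whole pair (both members, fresh
values and allocations) in the rare case it is not met, up to
`max_regenerations` (default 1000), recording the attempts used.

The value range is configurable. The printed defaults (8, 80) suit
age-in-years cohorts; `sct_config_for_trial()` derives a trial-specific
range as the pooled mean ± 3 widest-arm SDs, rounded outward to integers,
for baseline variables living on other scales.

By default `run_cohort()` generates a fresh confirmed pair per tested
trial, and records a per-trial seed so any single test can be re-run in
isolation; `shared_pair = TRUE` instead builds one confirmed pair and
reuses it across the cohort. Fresh-per-trial is the safer default: it
makes the per-trial results exchangeable and independent of cohort order.

## From reported summaries to mean/SD

The test needs mean, SD and N per arm. Reported summaries are normalized by
`normalize_arm()`:

* mean with SD: used as is;
* mean with SE: $SD = SE \sqrt{N}$. Such arms count as *directly* reported —
  only trials lacking a mean with SD or SE are deferred to the sensitivity
  analysis;
* median with min–max $(a, m, b)$: Hozo-style estimators,
  mean $= (a + 2m + b)/4$ and SD by sample-size branch —
  $\sqrt{\frac{1}{12}\left(\frac{(a - 2m + b)^2}{4} + (b - a)^2\right)}$
  for $n \le 15$, $(b - a)/4$ for $15 < n \le 70$, $(b - a)/6$ for
  $n > 70$. The three branches, including the small-sample formula, are all
  implemented; the thresholds 15 and 70 are the cited method's and are kept
  as package constants;
* median with IQR $(q_1, m, q_3)$: Wan-style estimators,
  mean $= (q_1 + m + q_3)/3$ and
  $SD = (q_3 - q_1) / \left(2\,\Phi^{-1}\!\frac{0.75n - 0.125}{n + 0.25}\right)$,
  with the quantile evaluated in full double precision (no table
  interpolation). For large $n$ this tends to the familiar IQR/1.349.

Median-converted arms carry `converted = TRUE`, so the main analysis
(`include_converted = FALSE`) can exclude them and the sensitivity analysis
(`include_converted = TRUE`) can add them back, without re-reading data.

For multi-arm trials, `select_most_divergent_arms()` picks the pair with
the largest two-sample z-statistic
$|m_i - m_j| / \sqrt{s_i^2/n_i + s_j^2/n_j}$ — an operationalization of
"the pair with the most significant baseline difference" — with ties broken
by first occurrence. This happens at cohort-preparation time; the cohort
CSV stores exactly one arm pair per trial.

## Auditing bias ratings against the test

Given RoB 2 ratings, each tested trial is classified with the rating as the
index judgment and the I2 test as the reference: TP (high-rated, positive),
TN (low-rated, negative), FN (low-rated, positive), FP (high-rated,
negative). Trials rated "some concerns" overall, or lacking a low/high
domain-1 rating, are skipped with a logged count — the low/high dichotomy
is part of the design, not an error condition.

Two headline statistics summarize the audit:

**False omission rate.** Literally $FOR = FN/(FN + TN)$, the probability
that a low-rated trial is actually test-positive. The package also provides
the prevalence-adjusted predictive-value form
$$FOR = \frac{(1 - Se)\,p}{Sp\,(1 - p) + (1 - Se)\,p},$$
with $Se = TP/(TP+FN)$, $Sp = TN/(TN+FP)$ and $p$ the prevalence of
test-positive trials. With the exact $p$ the two forms coincide
algebraically (the package property-tests this identity); they differ only
when $p$ is pre-rounded before entry, as diagnostic calculators commonly do.
`for_adjusted()` defaults to rounding the prevalence to one decimal in
percent — the convention under which published FOR figures derived from
such calculators reproduce exactly — and `prev_digits = NULL` gives the
literal value. Reports always show both estimators side by side and flag a
discrepancy rather than hiding it.

The 95% CI is the logit (delta-method) interval for $NPV = 1 - FOR$:
$\mathrm{var}(\operatorname{logit} NPV) = \frac{1-Sp}{Sp\,(TN+FP)} +
\frac{Se}{(1-Se)(TP+FN)}$, bounds
$\operatorname{logistic}(\operatorname{logit}(NPV) \mp z\sqrt{var})$ mapped
back to FOR. $z$ defaults to 1.959964. The interval is undefined at
boundary sensitivity or specificity and errors there; simulation at
$n = 1000$ with fixed margins shows near-nominal coverage.

**Negative likelihood ratio.** $-LR = (1 - Se)/Sp$, with the log-method
interval $\exp(\ln(-LR) \mp z\sqrt{Se/((1-Se)(TP+FN)) +
(1-Sp)/(Sp\,(TN+FP))})$. Interpretation bands ( `< 0.1` highly likely
bias-free, `0.1–0.2` moderately, `0.2–0.5` somewhat, `0.5–1.0` rarely) are
taken upper-closed at shared endpoints, so 0.5 falls in "somewhat"; values
above 1 are labelled *adverse* — the low-bias rating then makes high
selection-bias risk more, not less, likely.

`reference_counts()` stores the confusion tables of a published 1070-trial
audit (main analysis, two sensitivity reruns, domain-1 subgroup), and
`reference_diagnostics()` recomputes every headline statistic from those
counts alone.

## The synthetic cohort generator

Real audited cohorts are not redistributable, so `simulate_cohort()`
produces labelled stand-ins. Subject-level values are drawn from
$\mathcal{N}(\mu, \sigma)$ with defaults $\mu = 44$, $\sigma = 21$, chosen
to match the first two moments of the uniform(8, 80) SCT values so that
synthetic trials sit inside the default comparator range. Per-arm sizes are
uniform on 20–200, a realistic span for the mid-sized clinical trials such
audits encounter. Misallocation is modelled as a mean shift of
$\delta\sigma$ on one arm of a "biased" trial — the baseline-imbalance
footprint of non-random allocation; variance-inflating mechanisms are out
of scope. A fraction `biased_fraction` (default 0.078, mirroring observed
test-positive prevalence) of trials is biased; ratings contradict the truth
with probability `label_noise` (default 0.1), and the domain-1 rating is
unascertainable with probability `domain1_missing` (default 0.28, the
approximate share of trials without a low/high domain-1 rating in published
audits). Setting `median_fraction > 0` reports some arms as median-based
summaries to exercise the conversion path.

What the generator does *not* emulate: real baseline variables are often
skewed and integer-recorded; real rating errors are not independent
coin-flips but correlate with trial reporting quality; and real cohorts mix
baseline variables other than age with different scales. Passing tests on
synthetic cohorts therefore demonstrate the machinery's correctness and the
test's qualitative power behaviour (detection rising with $\delta$, seeded
determinism), not the field accuracy of the test on any particular real
corpus.

## Numerical and design choices

* All converters and pooling routines are pure functions; randomness enters
  only through R's seeded RNG in the SCT and cohort generators, and every
  cohort run records the per-trial seeds it used.
* $Q$ truncation: $I^2$ is set to 0 whenever $Q \le df$, and defined as 0
  at $Q = 0$; it is always `< 100`.
* Degenerate inputs error early and informatively: zero or negative SDs,
  `n < 2`, unordered median summaries, `q1 = q3` (SD would be 0), empty
  confusion-table margins, boundary sensitivities in interval formulas.
* The regeneration loop in `build_confirmed_sct_pair()` regenerates the
  *whole* pair rather than one member, keeping the two members
  exchangeable.
* Simulation sizes in the test suite — e.g. 6000 block draws, 2000
  confirmation attempts, 500 trials per misallocation level over
  $\delta \in \{0, 0.1, 0.2, 0.5, 1\}\sigma$, 600 interval-coverage
  replicates — were fixed in advance to keep Monte-Carlo standard errors
  small relative to the tested tolerances while the whole suite stays
  desk-scale.

## Limitations

The test's false-positive rate under a true null depends on arm sizes: the
trial's nominal variance enters the weights while the SCT anchors are
nearly noiseless, so small trials are tested against a laxer implicit
threshold than large ones. The audit statistics inherit the usual caveats
of diagnostic accuracy measures computed from a single cohort: the FOR
depends on prevalence, and a pre-rounded prevalence (the default, for
compatibility with published figures) introduces a small, explicit
discrepancy against the literal FN/(FN+TN). Finally, the generator's
independence assumptions make synthetic label noise more benign than real
rating error; operating characteristics on synthetic cohorts are
illustrative, not transportable to any specific clinical literature.
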