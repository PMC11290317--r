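#' Configuration of the simulated-comparator-trial generator
#'
#' A simulated comparator trial (SCT) is an artificial two-arm "trial":
#' integers drawn uniformly with replacement from `[lower, upper]` are sorted
#' ascending and paired position-by-position with a permuted-block
#' allocation sequence over groups A and B. The sorting couples the two arms
#' tightly, so an SCT pair pools to a homogeneous (I2 = 0) fixed-effect
#' meta-analysis with high probability and serves as the homogeneous anchor
#' the tested trial is inserted into.
#'
#' Defaults mirror the reference test procedure: values in `[8, 80]`
#' (age-like range in years), 200 values per SCT (100 per arm), block size 4.
#'
#' @param lower,upper Integer bounds of the value range, `lower < upper`.
#' @param count Number of values per SCT (even, divisible by `block_size`);
#'   each arm receives `count/2` subjects.
#' @param block_size Even block length of the permuted-block randomization.
#' @param max_regenerations Cap on regeneration attempts when confirming an
#'   I2 = 0 pair in [build_confirmed_sct_pair()].
#' @return An object of class `"sct_config"`.
#' @export
sct_config <- function(lower = 8L, upper = 80L, count = 200L,
                       block_size = 4L, max_regenerations = 1000L) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  count <- as.integer(count); block_size <- as.integer(block_size)
  if (lower >= upper) stop("need lower < upper", call. = FALSE)
  if (block_size < 2L || block_size %% 2L != 0L)
    stop("block_size must be a positive even integer", call. = FALSE)
  if (count < block_size || count %% block_size != 0L)
    stop("count must be divisible by block_size", call. = FALSE)
  if (max_regenerations < 1L)
    stop("max_regenerations must be positive", call. = FALSE)
  structure(list(lower = lower, upper = upper, count = count,
                 block_size = block_size,
                 max_regenerations = as.integer(max_regenerations)),
            class = "sct_config")
}

#' Derive an SCT value range from a tested trial
#'
#' Convenience mode tying the SCT range to the trial under test: bounds are
#' the pooled-arm mean plus/minus three pooled SDs, rounded to integers.
#'
#' @param arm_a,arm_b [arm_summary()] objects of the tested trial.
#' @param ... Further arguments passed to [sct_config()].
#' @return An `"sct_config"` with trial-specific `lower`/`upper`.
#' @export
sct_config_for_trial <- function(arm_a, arm_b, ...) {
  m <- (arm_a$mean * arm_a$n + arm_b$mean * arm_b$n) / (arm_a$n + arm_b$n)
  s <- max(arm_a$sd, arm_b$sd)
  sct_config(lower = floor(m - 3 * s), upper = ceiling(m + 3 * s), ...)
}

#' Permuted-block randomization sequence
#'
#' Generates an allocation sequence over labels A/B in consecutive blocks of
#' `block_size`, each an independent uniform draw from the balanced
#' arrangements (`block_size/2` of each label per block). Uses the current R
#' random number generator state.
#'
#' @param length Total sequence length, divisible by `block_size`.
#' @param block_size Even block length (default 4).
#' @return Character vector of `"A"`/`"B"` labels.
#' @export
block_randomize <- function(length, block_size = 4L) {
  length <- as.integer(length); block_size <- as.integer(block_size)
  if (block_size < 2L || block_size %% 2L != 0L)
    stop("block_size must be a positive even integer", call. = FALSE)
  if (length < 1L || length %% block_size != 0L)
    stop("length must be a positive multiple of block_size", call. = FALSE)
  n_blocks <- length %/% block_size
  base <- rep(c("A", "B"), each = block_size %/% 2L)
  unlist(lapply(seq_len(n_blocks), function(i) sample(base)),
         use.names = FALSE)
}

#' Sorted uniform integer draws for one SCT
#'
#' Draws `cfg$count` integers uniformly with replacement from
#' `[cfg$lower, cfg$upper]` and returns them sorted ascending — the value
#' column of an SCT sheet.
#'
#' @param cfg An [sct_config()].
#' @return Integer vector, non-decreasing.
#' @export
sample_sorted_values <- function(cfg) {
  stopifnot(inherits(cfg, "sct_config"))
  sort(sample(seq.int(cfg$lower, cfg$upper), cfg$count, replace = TRUE))
}

#' Build one simulated comparator trial
#'
#' Draws sorted values and a block-randomized allocation, pairs the i-th
#' sorted value with the i-th allocation label, and summarizes each arm with
#' the sample mean and SD (`n - 1` denominator).
#'
#' @param cfg An [sct_config()].
#' @return An object of class `"sct"`: list with `values`, `allocation`,
#'   `arm_a`, `arm_b`, `block_size`.
#' @export
build_sct <- function(cfg = sct_config()) {
  stopifnot(inherits(cfg, "sct_config"))
  values <- sample_sorted_values(cfg)
  alloc <- block_randomize(cfg$count, cfg$block_size)
  sct_from_values(values, alloc, cfg$block_size)
}

# Assemble an SCT from explicit values and allocation (shared by build_sct
# and tests that fix both columns by hand).
sct_from_values <- function(values, allocation, block_size = 4L) {
  stopifnot(length(values) == length(allocation),
            all(allocation %in% c("A", "B")))
  if (is.unsorted(values)) stop("values must be sorted ascending", call. = FALSE)
  va <- values[allocation == "A"]
  vb <- values[allocation == "B"]
  if (stats::sd(va) <= 0 || stats::sd(vb) <= 0)
    stop("degenerate SCT: an arm has zero SD", call. = FALSE)
  structure(list(values = as.integer(values), allocation = allocation,
                 arm_a = arm_summary(mean(va), stats::sd(va), length(va)),
                 arm_b = arm_summary(mean(vb), stats::sd(vb), length(vb)),
                 block_size = as.integer(block_size)),
            class = "sct")
}

#' @export
print.sct <- function(x, ...) {
  cat(sprintf("SCT: %d values in [%d, %d]\n", length(x$values),
              min(x$values), max(x$values)))
  cat("  A: "); print(x$arm_a)
  cat("  B: "); print(x$arm_b)
  invisible(x)
}

#' Serialize an SCT to its two-column CSV sheet
#' @param sct An `"sct"` object.
#' @param path Output path; columns `allocation`, `value`.
#' @return `path`, invisibly.
#' @export
write_sct <- function(sct, path) {
  utils::write.csv(data.frame(allocation = sct$allocation,
                              value = sct$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build an SCT pair confirmed to pool at I2 = 0
#'
#' Generates independent SCT pairs — fresh value and allocation draws for
#' each member — until the two-study fixed-effect meta-analysis of their arm
#' mean differences yields I2 = 0 exactly, i.e. `Q <= 1`. Because the
#' two-study Q is approximately chi-squared on 1 df under homogeneity, a
#' pair confirms per attempt with probability about `pchisq(1, 1) ~ 0.68`.
#'
#' @param cfg An [sct_config()]; `cfg$max_regenerations` caps the attempts.
#' @return List of class `"sct_pair"` with elements `sct1`, `sct2`,
#'   `attempts`, and `meta` (the confirming two-study [fixed_effect_pool()]).
#' @export
build_confirmed_sct_pair <- function(cfg = sct_config()) {
  stopifnot(inherits(cfg, "sct_config"))
  for (attempt in seq_len(cfg$max_regenerations)) {
    s1 <- build_sct(cfg)
    s2 <- build_sct(cfg)
    meta <- fixed_effect_pool(list(mean_difference_effect(s1$arm_a, s1$arm_b),
                                   mean_difference_effect(s2$arm_a, s2$arm_b)))
    if (meta$i2 == 0)
      return(structure(list(sct1 = s1, sct2 = s2, attempts = attempt,
                            meta = meta),
                       class = "sct_pair"))
  }
  stop("no I2 = 0 SCT pair within ", cfg$max_regenerations, " attempts",
       call. = FALSE)
}
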