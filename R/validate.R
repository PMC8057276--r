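#' Confusion counts for validation tallies
#'
#' @param tp,fp,fn,tn Non-negative counts (true/false positives/negatives).
#' @return A list of class `tn_confusion`.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L, tn = 0L) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0)) abort("confusion counts must be non-negative")
  structure(as.list(as.integer(v)), names = names(v), class = "tn_confusion")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Closed beta-quantile form: for x successes out of n at level `level`, the
#' lower bound is `qbeta(a/2, x, n - x + 1)` (0 when x = 0) and the upper
#' `qbeta(1 - a/2, x + 1, n - x)` (1 when x = n).
#'
#' @param x,n Successes and trials.
#' @param level Confidence level in (0, 1).
#' @return `list(estimate, ci_low, ci_high)`.
#' @export
binom_ci_cp <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, level > 0, level < 1)
  a <- 1 - level
  list(
    estimate = x / n,
    ci_low = if (x == 0) 0 else qbeta(a / 2, x, n - x + 1),
    ci_high = if (x == n) 1 else qbeta(1 - a / 2, x + 1, n - x)
  )
}

metric_row <- function(metric, x, n, level) {
  ci <- binom_ci_cp(x, n, level)
  out <- tibble(metric = metric, estimate = ci$estimate,
                ci_low = ci$ci_low, ci_high = ci$ci_high,
                level = level, method = "clopper_pearson",
                numerator = as.integer(x), denominator = as.integer(n))
  class(out) <- unique(c("tn_metric", class(out)))
  out
}

#' Analytic sensitivity with exact confidence interval
#'
#' `tp / (tp + fn)` with a Clopper-Pearson interval; invariant to tn.
#'
#' @param c A [confusion_counts()].
#' @param level Confidence level.
#' @return A one-row metric tibble (`estimate`, `ci_low`, `ci_high`, ...).
#' @examples
#' sensitivity(confusion_counts(tp = 26, fn = 2))  # 92.9% of 28
#' @export
sensitivity <- function(c, level = 0.95) {
  if (c$tp + c$fn == 0) abort("sensitivity undefined: tp + fn = 0")
  metric_row("sensitivity", c$tp, c$tp + c$fn, level)
}

#' Positive predictive value (the assay's operational analytic specificity)
#'
#' `tp / (tp + fp)` with a Clopper-Pearson interval.
#'
#' @inheritParams sensitivity
#' @return A one-row metric tibble.
#' @export
ppv <- function(c, level = 0.95) {
  if (c$tp + c$fp == 0) abort("PPV undefined: tp + fp = 0")
  metric_row("ppv", c$tp, c$tp + c$fp, level)
}

#' True-negative-rate specificity with exact confidence interval
#'
#' `tn / (tn + fp)`; complementary to the false positive rate.
#'
#' @inheritParams sensitivity
#' @return A one-row metric tibble.
#' @export
specificity <- function(c, level = 0.95) {
  if (c$tn + c$fp == 0) abort("specificity undefined: tn + fp = 0")
  metric_row("specificity", c$tn, c$tn + c$fp, level)
}

#' Squared Pearson correlation between expected and observed VAFs
#'
#' The concordance statistic used for accuracy studies against reference
#' standards with validated allele frequencies.
#'
#' @param expected,observed Equal-length numeric vectors (length >= 3).
#' @return r-squared in \[0, 1\].
#' @export
vaf_r_squared <- function(expected, observed) {
  if (length(expected) != length(observed) || length(expected) < 3L) {
    abort("need equal-length vectors of length >= 3")
  }
  if (stats::sd(expected) == 0 || stats::sd(observed) == 0) {
    abort("zero variance: r-squared undefined")
  }
  cor(expected, observed)^2
}

#' Score a call set against simulation truth
#'
#' A PASS call at a truly somatic site is a true positive; a PASS call at a
#' null or germline-het site is a false positive; a non-PASS somatic site is a
#' false negative; everything else is a true negative.
#'
#' @param calls A `tn_calls` table carrying the simulator's `truth_class`
#'   column (see [simulate_paired_counts()]).
#' @return A [confusion_counts()].
#' @export
score_calls <- function(calls) {
  if (!"truth_class" %in% names(calls)) {
    abort("calls must carry a truth_class column to be scored")
  }
  pos <- calls$filter_status == "PASS"
  som <- calls$truth_class == "somatic"
  confusion_counts(tp = sum(pos & som), fp = sum(pos & !som),
                   fn = sum(!pos & som), tn = sum(!pos & !som))
}

#' False-discovery proportion of a scored call set
#'
#' `fp / (tp + fp)`, defined as 0 when nothing is called.
#'
#' @param calls A `tn_calls` table with `truth_class`.
#' @return Fraction in \[0, 1\].
#' @export
false_discovery_proportion <- function(calls) {
  c <- score_calls(calls)
  if (c$tp + c$fp == 0) 0 else c$fp / (c$tp + c$fp)
}

#' Limit of detection from a dilution series
#'
#' The smallest expected VAF among dilution steps detected in every replicate;
#' `NA` when no step is consistently detected.
#'
#' @param series A `tn_dilution` table ([simulate_dilution_series()]), or any
#'   tibble with `expected_vaf`, `detected` and (optionally) `replicate`.
#' @return Numeric LOD, or `NA_real_`.
#' @export
lod_from_series <- function(series) {
  if (nrow(series) == 0L) abort("empty dilution series")
  by_step <- series |>
    group_by(.data$expected_vaf) |>
    summarise(all_detected = all(.data$detected), .groups = "drop")
  ok <- by_step$expected_vaf[by_step$all_detected]
  if (length(ok) == 0L) NA_real_ else min(ok)
}

#' Assemble a validation metrics table
#'
#' One row per supplied confusion-count set, formatted the way assay
#' validation reports print them (percent to one decimal with an exact CI).
#'
#' @param ... Named [confusion_counts()] objects, e.g.
#'   `snv = confusion_counts(...)`.
#' @param level Confidence level.
#' @return A tibble with sensitivity and PPV rows per assay component.
#' @export
validation_table <- function(..., level = 0.95) {
  sets <- list(...)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("confusion-count sets must be named")
  }
  purrr::imap(sets, function(c, nm) {
    rows <- list()
    if (c$tp + c$fn > 0) rows <- c(rows, list(sensitivity(c, level)))
    if (c$tp + c$fp > 0) rows <- c(rows, list(ppv(c, level)))
    dplyr::bind_rows(rows) |> mutate(component = nm, .before = 1)
  }) |>
    dplyr::bind_rows() |>
    mutate(display = sprintf("%.1f%% (CI %.1f-%.1f)", 100 * .data$estimate,
                             100 * .data$ci_low, 100 * .data$ci_high))
}
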