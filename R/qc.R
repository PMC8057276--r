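#' Run-level coverage metrics over targeted bases
#'
#' @param per_base_depth Non-empty integer vector of per-targeted-base depths.
#' @param uniformity_depth Depth threshold for the uniformity metric.
#' @return `list(mean_depth, uniformity)` where `uniformity` is the fraction
#'   of targeted bases at or above `uniformity_depth`.
#' @examples
#' coverage_metrics(c(50, 45, 30, 60))  # mean 46.25, uniformity 0.75 at 40x
#' @export
coverage_metrics <- function(per_base_depth, uniformity_depth = 40L) {
  if (length(per_base_depth) == 0L) abort("empty per-base depth vector")
  if (any(is.na(per_base_depth) | per_base_depth < 0)) {
    abort("depths must be non-negative")
  }
  list(mean_depth = mean(per_base_depth),
       uniformity = mean(per_base_depth >= uniformity_depth))
}

#' Assay quality-gate thresholds
#'
#' Defaults are the assay's run-level acceptance criteria: minimum mean depth
#' 240x tumor / 100x normal, >= 90% of targeted bases at 40x in each sample,
#' onboard Q30 >= 80%, and for runs with RNA >= 100 million total reads with
#' >= 50% aligned.
#'
#' @param min_depth_tumor,min_depth_normal Minimum mean target depth.
#' @param min_uniformity_40x Minimum fraction of targeted bases at >= 40x.
#' @param min_q30 Minimum fraction of bases at Q30 or better.
#' @param min_rna_reads Minimum total RNA reads (DNA+RNA mode).
#' @param min_rna_aligned Minimum aligned RNA read fraction (DNA+RNA mode).
#' @return A list of class `tn_qc_thresholds`.
#' @export
qc_thresholds <- function(min_depth_tumor = 240, min_depth_normal = 100,
                          min_uniformity_40x = 0.90, min_q30 = 0.80,
                          min_rna_reads = 1e8, min_rna_aligned = 0.50) {
  structure(
    list(min_depth_tumor = min_depth_tumor,
         min_depth_normal = min_depth_normal,
         min_uniformity_40x = min_uniformity_40x, min_q30 = min_q30,
         min_rna_reads = min_rna_reads, min_rna_aligned = min_rna_aligned),
    class = "tn_qc_thresholds"
  )
}

#' Gate a run against the assay quality thresholds
#'
#' Q30 and the RNA metrics are accepted as precomputed numbers (they are
#' produced sequencer-side); this function gates, it does not parse run files.
#' In `"dna"` mode the RNA gates are skipped. A missing required metric is an
#' error naming it; gating is monotone - improving any single metric never
#' turns a pass into a fail.
#'
#' @param report Named list/vector of metrics: `mean_depth_tumor`,
#'   `mean_depth_normal`, `uniformity_40x_tumor`, `uniformity_40x_normal`,
#'   `q30_fraction`, and in `"dna_rna"` mode also `total_rna_reads`,
#'   `rna_aligned_fraction`.
#' @param thresholds A [qc_thresholds()].
#' @param mode `"dna_rna"` (default) or `"dna"`.
#' @return A tibble of class `tn_qc` with one row per metric (`metric`,
#'   `value`, `threshold`, `pass`); attribute `pass` holds the overall gate.
#' @export
qc_gate <- function(report, thresholds = qc_thresholds(),
                    mode = c("dna_rna", "dna")) {
  mode <- match.arg(mode)
  report <- as.list(report)
  spec <- tibble(
    metric = c("mean_depth_tumor", "mean_depth_normal",
               "uniformity_40x_tumor", "uniformity_40x_normal",
               "q30_fraction", "total_rna_reads", "rna_aligned_fraction"),
    threshold = c(thresholds$min_depth_tumor, thresholds$min_depth_normal,
                  thresholds$min_uniformity_40x, thresholds$min_uniformity_40x,
                  thresholds$min_q30, thresholds$min_rna_reads,
                  thresholds$min_rna_aligned)
  )
  if (mode == "dna") spec <- spec[1:5, ]
  miss <- setdiff(spec$metric, names(report))
  if (length(miss) > 0) {
    abort(paste0("missing required QC metric(s): ", paste(miss, collapse = ", ")))
  }
  out <- spec |>
    mutate(value = vapply(.data$metric, function(m) as.numeric(report[[m]]),
                          numeric(1)),
           pass = .data$value >= .data$threshold) |>
    select("metric", "value", "threshold", "pass")
  attr(out, "pass") <- all(out$pass)
  class(out) <- unique(c("tn_qc", class(out)))
  out
}

#' @exportS3Method generics::glance
glance.tn_qc <- function(x, ...) {
  tibble(pass = attr(x, "pass"),
         n_metrics = nrow(x),
         failed = paste(x$metric[!x$pass], collapse = ","))
}

#' Fraction of bases at or above Q30 from FASTQ quality strings
#'
#' Convenience for synthetic tests; production Q30 is taken from the
#' sequencer's run metrics.
#'
#' @param qualities Character vector of Phred+33 quality strings.
#' @return Fraction of base calls with quality >= 30.
#' @export
q30_fraction <- function(qualities) {
  if (length(qualities) == 0L) abort("no quality strings")
  q <- unlist(lapply(qualities, function(s) utf8ToInt(s) - 33L))
  mean(q >= 30L)
}
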