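#' @importFrom ggplot2 ggplot aes geom_point geom_hline geom_vline geom_abline
#'   geom_line geom_smooth scale_x_log10 scale_y_log10 labs theme_minimal
#'   facet_wrap
NULL

#' Plot tumor vs normal VAF for a somatic call set
#'
#' Each point is a candidate site colored by filter status; the diagonal marks
#' equal allele fraction in the two samples (germline behaviour), dashed lines
#' the reporting VAF thresholds.
#'
#' @param object A `tn_calls` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tn_calls <- function(object, ...) {
  cfg <- attr(object, "config") %||% caller_config()
  ggplot(object, aes(x = .data$vaf_normal, y = .data$vaf_tumor,
                     colour = .data$filter_status)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    geom_hline(yintercept = c(cfg$vaf_min_hotspot, cfg$vaf_min_other),
               linetype = "dashed", colour = "grey40") +
    labs(x = "normal VAF", y = "tumor VAF", colour = "filter") +
    theme_minimal()
}

#' Plot expected vs observed VAF across a dilution series
#'
#' @param object A `tn_dilution` table ([simulate_dilution_series()]).
#' @param ... Unused.
#' @return A ggplot object (log-log axes, detection status as shape).
#' @exportS3Method ggplot2::autoplot
autoplot.tn_dilution <- function(object, ...) {
  ggplot(object, aes(x = .data$expected_vaf, y = pmax(.data$vaf_observed, 1e-4),
                     shape = .data$detected, colour = .data$detected)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    geom_point(alpha = 0.8) +
    scale_x_log10() + scale_y_log10() +
    labs(x = "expected VAF (1:1 dilution steps)", y = "observed VAF") +
    theme_minimal()
}

#' Plot gene-level focal copy-number calls
#'
#' Genes ordered along arms with focal log2 on the y axis; dashed lines mark
#' the amplification and deletion thresholds.
#'
#' @param object A `tn_cna` table ([call_genes()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tn_cna <- function(object, ...) {
  cfg <- attr(object, "config") %||% cna_config()
  d <- object |> arrange(.data$arm, .data$gene) |>
    mutate(idx = dplyr::row_number())
  ggplot(d, aes(x = .data$idx, y = .data$log2_focal, colour = .data$call)) +
    geom_point() +
    geom_hline(yintercept = c(cfg$amp_threshold, cfg$del_threshold),
               linetype = "dashed", colour = "grey40") +
    labs(x = "gene (ordered by arm)", y = "focal log2 ratio",
         colour = "call") +
    theme_minimal()
}

#' Expected vs observed VAF concordance plot
#'
#' Scatter with the least-squares line and the identity; the r-squared of the
#' fit is the concordance statistic reported by [vaf_r_squared()].
#'
#' @param expected,observed Equal-length numeric VAF vectors.
#' @return A ggplot object.
#' @export
plot_vaf_concordance <- function(expected, observed) {
  r2 <- vaf_r_squared(expected, observed)
  ggplot(tibble(expected = expected, observed = observed),
         aes(x = .data$expected, y = .data$observed)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "blue") +
    geom_smooth(method = "lm", formula = y ~ x, se = TRUE, colour = "black") +
    geom_point() +
    labs(x = "expected VAF", y = "observed VAF",
         title = sprintf("VAF concordance, r² = %.2f", r2)) +
    theme_minimal()
}
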