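#' Configuration for the somatic SNV/indel caller
#'
#' Defaults mirror the assay's informatic cutoffs: FDR controlled at 1% by
#' Benjamini-Hochberg, reporting VAF thresholds of 1% at hotspot sites and 5%
#' elsewhere, and depth minima of 240x tumor / 100x normal. Setting both VAF
#' minima to 0 disables the frequency filter (significance testing only).
#'
#' @param fdr_level Target false discovery rate in (0, 1).
#' @param vaf_min_hotspot,vaf_min_other Minimum reported tumor VAF at hotspot
#'   and non-hotspot sites; `vaf_min_hotspot <= vaf_min_other` is required.
#' @param min_tumor_depth,min_normal_depth Minimum per-site total depth; sites
#'   below either are flagged `low_depth` and excluded from the BH family.
#' @return A list of class `tn_caller_config`.
#' @export
caller_config <- function(fdr_level = 0.01,
                          vaf_min_hotspot = 0.01,
                          vaf_min_other = 0.05,
                          min_tumor_depth = 240L,
                          min_normal_depth = 100L) {
  stopifnot(fdr_level > 0, fdr_level < 1,
            vaf_min_hotspot >= 0, vaf_min_other >= 0,
            vaf_min_hotspot <= vaf_min_other,
            min_tumor_depth >= 0, min_normal_depth >= 0)
  structure(
    list(fdr_level = fdr_level,
         vaf_min_hotspot = vaf_min_hotspot,
         vaf_min_other = vaf_min_other,
         min_tumor_depth = as.integer(min_tumor_depth),
         min_normal_depth = as.integer(min_normal_depth)),
    class = "tn_caller_config"
  )
}

#' One-sided Fisher's exact test for tumor alt-allele enrichment
#'
#' For each site a 2x2 table of alt/ref haplotype counts in tumor and normal is
#' tested against the one-sided alternative that the alternative haplotype is
#' enriched in the tumor. The returned value is the exact hypergeometric tail
#' probability, conditional on the table margins, that the tumor alt count is
#' at least as large as observed. Vectorized over sites.
#'
#' @param alt_tumor,ref_tumor,alt_normal,ref_normal Non-negative counts, or a
#'   single `tn_sites` table passed as `alt_tumor`.
#' @return Numeric p-values in \[0, 1\]. An all-zero table yields 1 with a
#'   warning (no evidence either way).
#' @examples
#' fisher_one_sided(3, 0, 0, 3)   # 1/20: all alt reads landed in the tumor
#' @export
fisher_one_sided <- function(alt_tumor, ref_tumor = NULL,
                             alt_normal = NULL, ref_normal = NULL) {
  if (is.data.frame(alt_tumor)) {
    s <- alt_tumor
    return(fisher_one_sided(s$alt_tumor, s$ref_tumor, s$alt_normal, s$ref_normal))
  }
  at <- as.numeric(alt_tumor); rt <- as.numeric(ref_tumor)
  an <- as.numeric(alt_normal); rn <- as.numeric(ref_normal)
  if (any(c(at, rt, an, rn) < 0)) abort("counts must be non-negative")
  if (any(at + rt + an + rn == 0)) {
    warn("all-zero contingency table: returning p = 1 (no evidence)")
  }
  # P(X >= alt_tumor | margins): X ~ hypergeometric with alt reads as "white"
  p <- phyper(at - 1, m = at + an, n = rt + rn, k = at + rt, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Benjamini-Hochberg step-up adjustment and rejection set
#'
#' Standard BH: with ordered p-values p_(1) <= ... <= p_(m), reject the largest
#' k with p_(k) <= k * fdr / m and all smaller ranks. The reported q-values are
#' the monotone step-up adjusted p-values (`stats::p.adjust` method `"BH"`);
#' rejection is equivalent to `q <= fdr_level`. Output order matches input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param fdr_level Target FDR in (0, 1).
#' @return A tibble with columns `p_value`, `q_value`, `reject`.
#' @export
bh_adjust <- function(p_values, fdr_level = 0.01) {
  stopifnot(fdr_level > 0, fdr_level < 1)
  if (length(p_values) == 0L) {
    return(tibble(p_value = numeric(0), q_value = numeric(0),
                  reject = logical(0)))
  }
  if (any(is.na(p_values) | p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  q <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, q_value = q, reject = q <= fdr_level)
}

variant_class_of <- function(ref, alt) {
  dplyr::case_when(
    nchar(alt) > nchar(ref) ~ "insertion",
    nchar(alt) < nchar(ref) ~ "deletion",
    TRUE ~ "SNV"
  )
}

#' Call somatic SNVs and indels from paired tumor/normal counts
#'
#' Per site: tumor and normal VAFs and the one-sided Fisher exact p-value are
#' computed; sites passing the depth minima form a single BH family per sample
#' tested at `config$fdr_level`; rejected sites are then screened against the
#' hotspot-aware reporting VAF threshold. Filter status is exactly one of
#' `low_depth` (failed a depth minimum; excluded from the BH family, q-value
#' `NA`), `not_significant` (tested, not rejected), `below_vaf` (rejected but
#' tumor VAF below the applicable threshold) or `PASS`. Every input site
#' appears exactly once in the output, in input order.
#'
#' @param sites A `tn_sites` table ([site_counts()] / [read_site_counts()]).
#' @param hotspots Optional `tn_hotspots` table ([hotspot_list()]).
#' @param config A [caller_config()].
#' @return A tibble of class `tn_calls`: the site columns plus `depth_tumor`,
#'   `depth_normal`, `vaf_tumor`, `vaf_normal`, `p_value`, `q_value`,
#'   `is_hotspot`, `variant_class`, `filter_status`.
#' @export
call_somatic <- function(sites, hotspots = NULL, config = caller_config()) {
  sites <- validate_site_counts(sites)
  if (nrow(sites) == 0L) abort("no sites to test")
  dt <- sites$alt_tumor + sites$ref_tumor
  dn <- sites$alt_normal + sites$ref_normal
  calls <- sites |>
    mutate(
      depth_tumor = dt,
      depth_normal = dn,
      vaf_tumor = ifelse(dt > 0, .data$alt_tumor / dt, 0),
      vaf_normal = ifelse(dn > 0, .data$alt_normal / dn, 0),
      p_value = suppressWarnings(
        fisher_one_sided(.data$alt_tumor, .data$ref_tumor,
                         .data$alt_normal, .data$ref_normal)),
      is_hotspot = is_hotspot(sites, hotspots),
      variant_class = variant_class_of(.data$ref, .data$alt)
    )
  eligible <- calls$depth_tumor >= config$min_tumor_depth &
    calls$depth_normal >= config$min_normal_depth
  q <- rep(NA_real_, nrow(calls))
  reject <- rep(FALSE, nrow(calls))
  if (any(eligible)) {
    bh <- bh_adjust(calls$p_value[eligible], config$fdr_level)
    q[eligible] <- bh$q_value
    reject[eligible] <- bh$reject
  }
  vaf_min <- ifelse(calls$is_hotspot, config$vaf_min_hotspot, config$vaf_min_other)
  calls <- calls |>
    mutate(
      q_value = q,
      filter_status = dplyr::case_when(
        !eligible ~ "low_depth",
        !reject ~ "not_significant",
        .data$vaf_tumor < vaf_min ~ "below_vaf",
        TRUE ~ "PASS"
      )
    )
  attr(calls, "config") <- config
  class(calls) <- unique(c("tn_calls", class(calls)))
  calls
}

#' @exportS3Method generics::glance
glance.tn_calls <- function(x, ...) {
  tibble(
    n_sites = nrow(x),
    n_tested = sum(x$filter_status != "low_depth"),
    n_pass = sum(x$filter_status == "PASS"),
    n_below_vaf = sum(x$filter_status == "below_vaf"),
    n_low_depth = sum(x$filter_status == "low_depth"),
    n_hotspot_pass = sum(x$filter_status == "PASS" & x$is_hotspot),
    median_vaf_pass = median(x$vaf_tumor[x$filter_status == "PASS"])
  )
}
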