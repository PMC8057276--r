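with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

random_bases <- function(n, len = 1L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate paired tumor/normal allele counts with known truth
#'
#' The minimal generative model consistent with the assay's depth statements:
#' per-site depths are Poisson around the mean target coverages (400x tumor,
#' 180x normal), and alt counts are binomial - at somatic sites with the true
#' VAF in the tumor and the sequencing error rate in the normal, at germline
#' heterozygous sites with p = 0.5 in both samples, and at null (error-only)
#' sites with the error rate in both. The default error rate of 0.2% keeps the
#' null alt fraction well below the 1% hotspot reporting threshold. Truth is
#' carried in `truth_class` / `true_vaf` columns so sensitivity, specificity
#' and false-discovery proportions can be scored exactly.
#'
#' @param n_sites Number of candidate sites.
#' @param somatic_fraction,germline_fraction Fractions of sites that are truly
#'   somatic / germline-het; the remainder are error-only nulls.
#' @param vaf_sampler Function `n -> n` true somatic VAFs (default uniform on
#'   \[0.10, 0.30\]).
#' @param depth_tumor,depth_normal Mean depths (Poisson).
#' @param error_rate Per-read error alt probability.
#' @param seed Optional integer seed; the same seed reproduces the table
#'   bit-identically.
#' @return A `tn_sites` tibble with extra columns `truth_class`
#'   (`"somatic"|"germline_het"|"null"`) and `true_vaf` (`NA` off somatic).
#' @export
simulate_paired_counts <- function(n_sites,
                                   somatic_fraction = 0.05,
                                   germline_fraction = 0.05,
                                   vaf_sampler = function(n) runif(n, 0.10, 0.30),
                                   depth_tumor = 400,
                                   depth_normal = 180,
                                   error_rate = 0.002,
                                   seed = NULL) {
  stopifnot(n_sites >= 1, somatic_fraction >= 0, germline_fraction >= 0,
            somatic_fraction + germline_fraction <= 1,
            error_rate >= 0, error_rate < 1)
  with_seed_maybe(seed, {
    n_som <- round(n_sites * somatic_fraction)
    n_germ <- round(n_sites * germline_fraction)
    cls <- sample(rep(c("somatic", "germline_het", "null"),
                      c(n_som, n_germ, n_sites - n_som - n_germ)))
    true_vaf <- rep(NA_real_, n_sites)
    true_vaf[cls == "somatic"] <- vaf_sampler(sum(cls == "somatic"))
    dt <- rpois(n_sites, depth_tumor)
    dn <- rpois(n_sites, depth_normal)
    p_t <- ifelse(cls == "somatic", true_vaf,
                  ifelse(cls == "germline_het", 0.5, error_rate))
    p_n <- ifelse(cls == "germline_het", 0.5, error_rate)
    at <- rbinom(n_sites, dt, p_t)
    an <- rbinom(n_sites, dn, p_n)
    ref <- random_bases(n_sites)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1), USE.NAMES = FALSE)
    out <- site_counts(chrom = "chr1", pos = seq_len(n_sites) * 100L,
                       ref = ref, alt = alt,
                       alt_tumor = at, ref_tumor = dt - at,
                       alt_normal = an, ref_normal = dn - an)
    out$truth_class <- cls
    out$true_vaf <- true_vaf
    out
  })
}

#' Simulate a 1:1 serial dilution series and run the caller on each step
#'
#' Emulates the limit-of-detection protocol: a tumor carrying a variant at
#' `base_vaf` is mixed 1:1 with its germline down to `1:2^k_max` (1:64 by
#' default), halving the expected VAF at each step. Each replicate of each
#' step is simulated as one sequenced site and analyzed with [call_somatic()]
#' as its own single-site family; `detected` records a PASS call.
#'
#' @param base_vaf Undiluted VAF in (0, 1\].
#' @param k_max Last dilution exponent (step k has expected VAF
#'   `base_vaf / 2^k`).
#' @param depth,depth_normal Mean tumor/normal depths (Poisson).
#' @param error_rate Alt probability in the normal.
#' @param replicates Independent replicates per step.
#' @param hotspot Whether the diluted variant is a hotspot (1% VAF threshold).
#' @param config A [caller_config()].
#' @param seed Optional integer seed.
#' @return A tibble of class `tn_dilution`: `replicate, step, dilution,
#'   expected_vaf`, the simulated counts, `vaf_observed, p_value,
#'   filter_status, detected`.
#' @export
simulate_dilution_series <- function(base_vaf, k_max = 6L, depth = 400,
                                     depth_normal = 180, error_rate = 0.002,
                                     replicates = 1L, hotspot = TRUE,
                                     config = caller_config(), seed = NULL) {
  stopifnot(base_vaf > 0, base_vaf <= 1, k_max >= 0, replicates >= 1)
  with_seed_maybe(seed, {
    grid <- tidyr::expand_grid(replicate = seq_len(replicates),
                               step = 0:k_max)
    grid$dilution <- 2^grid$step
    grid$expected_vaf <- base_vaf / grid$dilution
    n <- nrow(grid)
    dt <- rpois(n, depth)
    dn <- rpois(n, depth_normal)
    at <- rbinom(n, dt, grid$expected_vaf)
    an <- rbinom(n, dn, error_rate)
    out <- purrr::pmap(
      list(at, dt, an, dn, grid$expected_vaf),
      function(at1, dt1, an1, dn1, ev) {
        s <- site_counts("chr1", 1000L, "C", "T",
                         at1, dt1 - at1, an1, dn1 - an1)
        hs <- if (hotspot) hotspot_list("chr1", 1000L, "C", "T") else NULL
        call <- call_somatic(s, hotspots = hs, config = config)
        tibble(alt_tumor = at1, depth_tumor = dt1,
               alt_normal = an1, depth_normal = dn1,
               vaf_observed = call$vaf_tumor,
               p_value = call$p_value,
               filter_status = call$filter_status,
               detected = call$filter_status == "PASS")
      })
    out <- dplyr::bind_cols(grid, dplyr::bind_rows(out))
    class(out) <- unique(c("tn_dilution", class(out)))
    out
  })
}

bias_fun <- function(bias, which) {
  if (is.null(bias)) return(function(x) rep(1, NROW(x)))
  if (is.function(bias)) return(bias)
  if (is.list(bias) && !is.null(bias[[which]])) return(bias[[which]])
  function(x) rep(1, NROW(x))
}

#' Simulate a biased per-target coverage track with known copy states
#'
#' Targets are grouped into genes on chromosome arms; tumor counts are
#' negative binomial with mean proportional to
#' `copy_state/2 x gc_bias(gc) x dinuc_bias(profile) x mean_depth` (the normal
#' is always diploid). Bias functions may differ between samples (pass
#' `list(tumor = f, normal = g)`) to emulate FFPE-specific fragmentation and
#' capture effects; covariates are recorded so the normalizer can be tested
#' for bias removal. `dispersion = 0` gives Poisson counts.
#'
#' @param n_genes,targets_per_gene,n_arms Track layout. Defaults (8 targets
#'   per gene) reflect a typical exon count per gene in exome capture.
#' @param copy_states Named numeric vector of true copy states per gene
#'   (names matching the generated `GENE###` ids); unnamed genes are diploid.
#' @param gc_bias,dinuc_bias `NULL`, a function, or `list(tumor=, normal=)`.
#'   `gc_bias` maps the GC fraction vector to multiplicative factors;
#'   `dinuc_bias` maps the 16-column composition matrix to factors.
#' @param mean_depth Mean diploid target coverage.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); default 0.02 is moderate FFPE overdispersion.
#' @param seed Optional integer seed.
#' @return A target tibble (see [normalize_coverage()]) with a truth
#'   `copy_state` column.
#' @export
simulate_coverage_track <- function(n_genes = 100L, targets_per_gene = 8L,
                                    n_arms = 10L, copy_states = NULL,
                                    gc_bias = NULL, dinuc_bias = NULL,
                                    mean_depth = 400, dispersion = 0.02,
                                    seed = NULL) {
  stopifnot(n_genes >= 1, targets_per_gene >= 1, n_arms >= 1,
            mean_depth > 0, dispersion >= 0)
  with_seed_maybe(seed, {
    genes <- sprintf("GENE%03d", seq_len(n_genes))
    arm_of <- paste0("arm", sprintf("%02d", ((seq_len(n_genes) - 1L) %% n_arms) + 1L))
    cs <- setNames(rep(2, n_genes), genes)
    if (!is.null(copy_states)) cs[names(copy_states)] <- copy_states
    n <- n_genes * targets_per_gene
    gi <- rep(seq_len(n_genes), each = targets_per_gene)
    gc <- runif(n, 0.3, 0.7)
    dmat <- matrix(rgamma(n * 16L, shape = 2), nrow = n)
    dmat <- dmat / rowSums(dmat)
    colnames(dmat) <- dinucleotides()
    bt_gc <- bias_fun(gc_bias, "tumor")(gc)
    bn_gc <- bias_fun(gc_bias, "normal")(gc)
    bt_dn <- bias_fun(dinuc_bias, "tumor")(dmat)
    bn_dn <- bias_fun(dinuc_bias, "normal")(dmat)
    mu_t <- mean_depth * (cs[gi] / 2) * bt_gc * bt_dn
    mu_n <- mean_depth * bn_gc * bn_dn
    draw <- function(mu) {
      if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
      else rpois(n, mu)
    }
    start <- (seq_len(n) - 1L) * 500L + (gi - 1L) * 100L
    out <- tibble(
      chrom = paste0("chr", match(arm_of[gi], unique(arm_of))),
      start = start, end = start + 120L,
      gene = genes[gi], arm = arm_of[gi],
      gc_fraction = gc
    )
    out <- dplyr::bind_cols(out, as_tibble(dmat))
    out$raw_tumor <- draw(mu_t)
    out$raw_normal <- draw(mu_n)
    out$copy_state <- unname(cs[gi])
    out
  })
}

primitive_unit <- function(len) {
  repeat {
    u <- random_bases(1, len)
    chars <- strsplit(u, "")[[1]]
    if (len == 1L) return(u)
    if (length(unique(chars)) == 1L) next           # power of a mono unit
    if (len == 3L) return(u)
    return(u)                                       # len 2, two distinct bases
  }
}

qualifies_msi <- function(ref, alt, window, anchor, min_unit_copies = 3L) {
  rc <- repeat_context(ref, alt, window, anchor)
  !is.na(rc$repeat_unit) && rc$unit_copies >= min_unit_copies
}

#' Simulate tumor-specific indels in and out of short tandem repeats
#'
#' Plants `n_repeat_indels` insertions/deletions of whole repeat units inside
#' generated tandem runs (unit length 1-3 bp, at least 3 copies) and
#' `n_nonrepeat_indels` indels in non-repetitive sequence, each with its
#' +/-`window_flank` bp reference window. Generation is rejection-sampled
#' against the repeat annotator so the planted truth tally is exactly
#' `n_repeat_indels`.
#'
#' @param n_repeat_indels,n_nonrepeat_indels Row counts (>= 0).
#' @param unit_length_mix Sampling weights for unit lengths 1, 2, 3.
#' @param copies_range Tandem copy numbers to draw runs from.
#' @param window_flank Flank length on each side of the indel.
#' @param seed Optional integer seed.
#' @return A tibble of PASS indel calls with `local_reference`, `window_pos`
#'   and a truth column `truth_repeat`.
#' @export
simulate_msi_indels <- function(n_repeat_indels, n_nonrepeat_indels,
                                unit_length_mix = c(0.6, 0.25, 0.15),
                                copies_range = 3:8, window_flank = 20L,
                                seed = NULL) {
  stopifnot(n_repeat_indels >= 0, n_nonrepeat_indels >= 0,
            length(unit_length_mix) == 3L, all(copies_range >= 3L))
  one_repeat <- function() {
    for (i in 1:1000) {
      L <- sample(1:3, 1, prob = unit_length_mix)
      unit <- primitive_unit(L)
      cp <- sample(rep(copies_range, 2L), 1)
      run <- strrep(unit, cp)
      left <- random_bases(1, window_flank)
      right <- random_bases(1, window_flank)
      window <- paste0(left, run, right)
      anchor <- window_flank
      anchor_base <- substr(window, anchor, anchor)
      if (runif(1) < 0.5) {
        ref <- paste0(anchor_base, unit); alt <- anchor_base   # deletion
      } else {
        ref <- anchor_base; alt <- paste0(anchor_base, unit)   # insertion
      }
      rc <- repeat_context(ref, alt, window, anchor)
      expected <- cp + (nchar(alt) > nchar(ref))
      # accept only when flanks neither extend nor rephase the planted run
      if (!is.na(rc$repeat_unit) && rc$repeat_unit == unit &&
          rc$unit_copies == expected && rc$unit_copies >= 3L) {
        return(tibble(ref = ref, alt = alt, local_reference = window,
                      window_pos = anchor, truth_repeat = TRUE))
      }
    }
    abort("failed to generate a repeat-context indel")
  }
  one_nonrepeat <- function() {
    for (i in 1:1000) {
      len <- sample(1:4, 1)
      seq <- random_bases(1, len)
      left <- random_bases(1, window_flank)
      right <- random_bases(1, window_flank)
      anchor <- window_flank
      if (runif(1) < 0.5) {
        window <- paste0(left, seq, right)
        anchor_base <- substr(window, anchor, anchor)
        ref <- paste0(anchor_base, seq); alt <- anchor_base
      } else {
        window <- paste0(left, right)
        anchor_base <- substr(window, anchor, anchor)
        ref <- anchor_base; alt <- paste0(anchor_base, seq)
      }
      if (!qualifies_msi(ref, alt, window, anchor)) {
        return(tibble(ref = ref, alt = alt, local_reference = window,
                      window_pos = anchor, truth_repeat = FALSE))
      }
    }
    abort("failed to generate a non-repeat indel")
  }
  with_seed_maybe(seed, {
    rows <- c(purrr::map(seq_len(n_repeat_indels), ~one_repeat()),
              purrr::map(seq_len(n_nonrepeat_indels), ~one_nonrepeat()))
    out <- dplyr::bind_rows(rows)
    if (nrow(out) == 0L) {
      out <- tibble(ref = character(), alt = character(),
                    local_reference = character(), window_pos = integer(),
                    truth_repeat = logical())
    }
    n <- nrow(out)
    dplyr::bind_cols(
      tibble(chrom = rep("chr1", n), pos = seq_len(n) * 1000L,
             variant_class = ifelse(nchar(out$alt) > nchar(out$ref),
                                    "insertion", "deletion")[seq_len(n)],
             filter_status = rep("PASS", n)),
      out
    )
  })
}
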