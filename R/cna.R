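#' Configuration for focal copy-number calling
#'
#' Call thresholds act on the arm-adjusted (focal) log2 ratio. The defaults
#' place the decision boundaries at the midpoints separating the minimal
#' reportable event from the nearest non-reportable copy state in a pure
#' diploid tumor: amplification at +0.75 (between a 3-copy gain, log2 0.585,
#' and the minimal reportable 4-copy gain, log2 1.0) and deletion at -0.5
#' (between neutral, log2 0, and single-copy loss, log2 -1). Putting the
#' boundary between states rather than on one keeps the minimal event
#' detectable under sampling noise. No purity correction is applied; with
#' lower tumor content all log2 ratios shrink toward 0 and the thresholds
#' become conservative.
#'
#' @param amp_threshold Focal log2 at or above which a gene is called
#'   amplified (> 0).
#' @param del_threshold Focal log2 at or below which a gene is called
#'   deleted (< 0).
#' @param min_targets_per_gene Genes with fewer targets are reported neutral
#'   with `low_evidence = TRUE`.
#' @param pseudocount Added to both normalized counts inside the log2 ratio to
#'   guard zero coverage.
#' @param gc_bins Number of GC-fraction quantile bins for coverage correction.
#' @return A list of class `tn_cna_config`.
#' @export
cna_config <- function(amp_threshold = 0.75, del_threshold = -0.5,
                       min_targets_per_gene = 3L, pseudocount = 1,
                       gc_bins = 20L) {
  stopifnot(amp_threshold > 0, del_threshold < 0, pseudocount > 0,
            min_targets_per_gene >= 1, gc_bins >= 2)
  structure(
    list(amp_threshold = amp_threshold, del_threshold = del_threshold,
         min_targets_per_gene = as.integer(min_targets_per_gene),
         pseudocount = pseudocount, gc_bins = as.integer(gc_bins)),
    class = "tn_cna_config"
  )
}

#' The 16 dinucleotide column names used in target tables
#' @return Character vector `dinuc_AA` ... `dinuc_TT`.
#' @export
dinucleotides <- function() {
  b <- c("A", "C", "G", "T")
  paste0("dinuc_", as.vector(outer(b, b, paste0)))
}

validate_targets <- function(targets, need_norm = FALSE) {
  need <- c("chrom", "start", "end", "gene", "arm", "gc_fraction",
            "raw_tumor", "raw_normal")
  if (need_norm) need <- c(need, "norm_tumor", "norm_normal")
  miss <- setdiff(need, names(targets))
  if (length(miss) > 0) {
    abort(paste0("target table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(targets$end <= targets$start)) abort("targets need end > start")
  if (any(targets$gc_fraction < 0 | targets$gc_fraction > 1)) {
    abort("gc_fraction must lie in [0, 1]")
  }
  as_tibble(targets)
}

#' Insert-size distribution matching weights
#'
#' Computes per-fragment weights that reweight both samples' fragment-length
#' histograms onto their common envelope `min(h_t, h_n)` per bin, so the
#' reweighted distributions are identical and alignment bias between samples
#' is minimized. Weight for a fragment in bin b of sample s is
#' `min(h_t[b], h_n[b]) / h_s[b]` (0 where the sample has no mass).
#'
#' @param tumor_inserts,normal_inserts Numeric histograms over the same bin
#'   grid (equal length; names, if any, must agree).
#' @return A tibble with columns `bin`, `weight_tumor`, `weight_normal`.
#' @export
match_insert_size <- function(tumor_inserts, normal_inserts) {
  if (length(tumor_inserts) != length(normal_inserts) || length(tumor_inserts) == 0L) {
    abort("histograms must be nonempty and on the same bin grid")
  }
  if (!is.null(names(tumor_inserts)) && !is.null(names(normal_inserts)) &&
      !identical(names(tumor_inserts), names(normal_inserts))) {
    abort("histogram bin labels disagree")
  }
  lo <- pmin(tumor_inserts, normal_inserts)
  if (all(lo == 0)) abort("insert-size supports are disjoint; samples incomparable")
  w <- function(h) ifelse(h > 0, lo / h, 0)
  tibble(
    bin = names(tumor_inserts) %||% seq_along(tumor_inserts),
    weight_tumor = w(tumor_inserts),
    weight_normal = w(normal_inserts)
  )
}

## per-sample normalization: library scaling, GC quantile-bin median factors,
## robust dinucleotide regression on log-scale residuals
normalize_one <- function(counts, gc, dinuc, config) {
  x <- counts * (1e6 / sum(counts))             # counts per million
  # GC correction: quantile bins, factor = bin median / global median
  br <- unique(quantile(gc, probs = seq(0, 1, length.out = config$gc_bins + 1L),
                        names = FALSE))
  bin <- if (length(br) > 2L) {
    cut(gc, breaks = br, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, length(gc))
  gmed <- median(x)
  fac <- tapply(x, bin, median)[as.character(bin)] / gmed
  zero <- is.na(fac) | fac <= 0
  if (any(zero)) {
    warn("GC bin with non-positive median coverage; factor set to 1")
    fac[zero] <- 1
  }
  x <- x / fac
  # dinucleotide correction: robust fit of log residuals on composition
  if (!is.null(dinuc) && nrow(dinuc) == length(x) && ncol(dinuc) >= 2L) {
    r <- log(x + config$pseudocount)
    d <- as.matrix(dinuc[, -ncol(dinuc), drop = FALSE])  # drop one: rows sum to 1
    fit <- tryCatch(
      MASS::rlm(r - median(r) ~ d, maxit = 100),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      adj <- fitted(fit) - mean(fitted(fit))   # centered: preserves scale
      x <- exp(r - adj) - config$pseudocount
      x <- pmax(x, 0)
    }
  }
  unname(as.numeric(x))
}

#' Normalize per-target coverage for library size, GC and dinucleotide bias
#'
#' Applied independently to tumor and normal: (1) library-size scaling to a
#' common total (counts per million, so multiplying all raw counts of a sample
#' by a constant leaves the result unchanged); (2) GC correction by dividing
#' each target by the median coverage of its GC quantile bin relative to the
#' global median (monotone-safe, controls capture-efficiency differences);
#' (3) dinucleotide correction by a robust linear fit (`MASS::rlm`) of
#' log-coverage residuals on the 16 dinucleotide composition fractions,
#' subtracting the centered fit (controls FFPE fragmentation bias). Row order
#' is preserved; `norm_tumor`/`norm_normal` columns are added.
#'
#' @param targets Target table with `chrom,start,end,gene,arm,gc_fraction`,
#'   the 16 [dinucleotides()] columns (optional), and `raw_tumor,raw_normal`.
#' @param config A [cna_config()].
#' @return `targets` with `norm_tumor` and `norm_normal` filled in.
#' @export
normalize_coverage <- function(targets, config = cna_config()) {
  targets <- validate_targets(targets)
  if (nrow(targets) < config$gc_bins) {
    abort(paste0("need at least gc_bins = ", config$gc_bins, " targets"))
  }
  dn <- intersect(dinucleotides(), names(targets))
  dmat <- if (length(dn) == 16L) targets[, dn] else NULL
  targets$norm_tumor <- normalize_one(targets$raw_tumor, targets$gc_fraction,
                                      dmat, config)
  targets$norm_normal <- normalize_one(targets$raw_normal, targets$gc_fraction,
                                       dmat, config)
  targets
}

#' Per-target tumor/normal log2 coverage ratio
#'
#' `log2((norm_tumor + pseudocount) / (norm_normal + pseudocount))` for every
#' target; the pseudocount keeps zero-coverage targets finite.
#'
#' @param targets A normalized target table ([normalize_coverage()]).
#' @param pseudocount Positive guard value; defaults to the [cna_config()]
#'   default.
#' @return `targets` with a `log2_ratio` column added.
#' @export
target_log2 <- function(targets, pseudocount = 1) {
  targets <- validate_targets(targets, need_norm = TRUE)
  stopifnot(pseudocount > 0)
  targets$log2_ratio <- log2((targets$norm_tumor + pseudocount) /
                               (targets$norm_normal + pseudocount))
  targets
}

#' Gene-level focal copy-number calls with chromosome-arm adjustment
#'
#' Per gene, `log2_gene` is the median target log2 ratio; `log2_arm` is the
#' median over all targets on the gene's chromosome arm; their difference
#' `log2_focal` separates focal events from arm-level/ploidy shifts. Calls are
#' thresholded on `log2_focal`: amplification at `>= amp_threshold`, deletion
#' at `<= del_threshold`, else neutral. Genes with fewer than
#' `min_targets_per_gene` targets are reported neutral with
#' `low_evidence = TRUE`.
#'
#' @param targets Target table; normalized and log2 columns are computed here
#'   if absent.
#' @param config A [cna_config()].
#' @return A tibble of class `tn_cna`: `gene, arm, n_targets, log2_gene,
#'   log2_arm, log2_focal, call, low_evidence`.
#' @export
call_genes <- function(targets, config = cna_config()) {
  if (!all(c("norm_tumor", "norm_normal") %in% names(targets))) {
    targets <- normalize_coverage(targets, config)
  }
  if (!"log2_ratio" %in% names(targets)) {
    targets <- target_log2(targets, config$pseudocount)
  }
  if (any(is.na(targets$gene) | is.na(targets$arm))) {
    abort("every target must carry gene and arm labels")
  }
  arm_med <- targets |>
    group_by(.data$arm) |>
    summarise(log2_arm = median(.data$log2_ratio), .groups = "drop")
  out <- targets |>
    group_by(.data$gene, .data$arm) |>
    summarise(n_targets = dplyr::n(),
              log2_gene = median(.data$log2_ratio), .groups = "drop") |>
    left_join(arm_med, by = "arm") |>
    mutate(
      log2_focal = .data$log2_gene - .data$log2_arm,
      low_evidence = .data$n_targets < config$min_targets_per_gene,
      call = dplyr::case_when(
        .data$low_evidence ~ "neutral",
        .data$log2_focal >= config$amp_threshold ~ "amplification",
        .data$log2_focal <= config$del_threshold ~ "deletion",
        TRUE ~ "neutral"
      )
    ) |>
    select("gene", "arm", "n_targets", "log2_gene", "log2_arm",
           "log2_focal", "call", "low_evidence")
  attr(out, "config") <- config
  class(out) <- unique(c("tn_cna", class(out)))
  out
}

#' @exportS3Method generics::glance
glance.tn_cna <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_amplified = sum(x$call == "amplification"),
    n_deleted = sum(x$call == "deletion"),
    n_low_evidence = sum(x$low_evidence)
  )
}

#' Write per-gene coverage segments in SEG-style TSV
#'
#' One row per gene spanning its targets: `chrom, start, end, gene,
#' n_targets, log2`.
#'
#' @param targets Target table with `log2_ratio` (see [target_log2()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(targets, path) {
  seg <- targets |>
    group_by(.data$chrom, .data$gene) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_targets = dplyr::n(), log2 = median(.data$log2_ratio),
              .groups = "drop") |>
    select("chrom", "start", "end", "gene", "n_targets", "log2") |>
    arrange(.data$chrom, .data$start)
  readr::write_tsv(seg, path)
  invisible(path)
}
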