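#' TMB category boundaries
#'
#' Mutational burden below `low_upper` mut/Mb is Low, at or above `high_lower`
#' is High, in between Intermediate; the half-open closure
#' `Low < 5 <= Intermediate < 20 <= High` makes the three categories a
#' partition of the non-negative line.
#'
#' @param low_upper Upper boundary of Low (mut/Mb).
#' @param high_lower Lower boundary of High (mut/Mb).
#' @return A list of class `tn_tmb_config`.
#' @export
tmb_config <- function(low_upper = 5, high_lower = 20) {
  stopifnot(low_upper > 0, high_lower > low_upper)
  structure(list(low_upper = low_upper, high_lower = high_lower),
            class = "tn_tmb_config")
}

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open on disk; intervals are converted to 1-based
#' inclusive coordinates on read (via `rtracklayer`).
#'
#' @param path Path to a plain-text BED file.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr),
         end = GenomicRanges::end(gr))
}

regions_to_granges <- function(regions) {
  if (methods::is(regions, "GRanges")) return(regions)
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start, end = regions$end)
  )
}

#' Tumor mutational burden score and class
#'
#' TMB is the number of coding somatic alterations per megabase of target
#' space: PASS calls (all variant classes, synonymous included unless
#' pre-filtered by the caller of this function) whose position falls in a
#' coding interval, divided by the coding target space in Mb. When
#' `target_space_mb` is not supplied it is taken as the merged length of
#' `coding_regions`.
#'
#' @param calls A `tn_calls` table ([call_somatic()]).
#' @param coding_regions Coding intervals: a tibble `chrom,start,end`
#'   (1-based inclusive, e.g. from [read_bed()]) or a `GRanges`.
#' @param target_space_mb Positive denominator in megabases, or `NULL` to use
#'   the merged interval length.
#' @param config A [tmb_config()].
#' @return A list of class `tn_tmb`: `n_coding_somatic`, `target_space_mb`,
#'   `tmb`, `category`.
#' @examples
#' \dontrun{compute_tmb(calls, coding, target_space_mb = 35)}
#' @export
compute_tmb <- function(calls, coding_regions, target_space_mb = NULL,
                        config = tmb_config()) {
  gr <- regions_to_granges(coding_regions)
  if (length(gr) == 0L) abort("coding_regions is empty")
  if (is.null(target_space_mb)) {
    target_space_mb <- sum(GenomicRanges::width(GenomicRanges::reduce(gr))) / 1e6
  }
  if (!is.numeric(target_space_mb) || target_space_mb <= 0) {
    abort("target_space_mb must be positive")
  }
  pass <- calls[calls$filter_status == "PASS", , drop = FALSE]
  n <- if (nrow(pass) == 0L) 0L else {
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(pass$chrom,
                             IRanges::IRanges(pass$pos, pass$pos)),
      gr
    )
    length(unique(S4Vectors::queryHits(hits)))
  }
  tmb <- n / target_space_mb
  category <- if (tmb < config$low_upper) "Low"
  else if (tmb >= config$high_lower) "High"
  else "Intermediate"
  structure(
    list(n_coding_somatic = as.integer(n),
         target_space_mb = target_space_mb,
         tmb = tmb, category = category),
    class = "tn_tmb"
  )
}

#' @export
print.tn_tmb <- function(x, ...) {
  cat(sprintf("TMB: %.2f mut/Mb (%d coding somatic / %.2f Mb) - %s\n",
              x$tmb, x$n_coding_somatic, x$target_space_mb, x$category))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tn_tmb <- function(x, ...) {
  tibble(n_coding_somatic = x$n_coding_somatic,
         target_space_mb = x$target_space_mb,
         tmb = x$tmb, category = x$category)
}
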