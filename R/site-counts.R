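#' Build a validated table of per-site tumor/normal allele counts
#'
#' A site-counts table is the input boundary of the somatic caller: one row per
#' candidate variant site holding the four cells of the tumor/normal x alt/ref
#' contingency table. Haplotype extraction (alignment, base-quality filtering,
#' local assembly) is upstream of this package; counts are accepted as given.
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions (VCF convention).
#' @param ref,alt Reference and alternative alleles (non-empty, unequal).
#' @param alt_tumor,ref_tumor,alt_normal,ref_normal Non-negative read counts
#'   supporting the alternative / reference haplotype in each sample.
#' @return A tibble of class `tn_sites` with the eight columns above.
#' @examples
#' site_counts("chr7", 55249071, "C", "T", 40, 360, 0, 180)
#' @export
site_counts <- function(chrom, pos, ref, alt,
                        alt_tumor, ref_tumor, alt_normal, ref_normal) {
  x <- tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    alt_tumor = as.integer(alt_tumor), ref_tumor = as.integer(ref_tumor),
    alt_normal = as.integer(alt_normal), ref_normal = as.integer(ref_normal)
  )
  validate_site_counts(x)
}

#' Validate a site-counts table
#'
#' Checks the invariants of the site-counts contract: required columns, all
#' counts non-negative, positions >= 1, and `ref != alt` everywhere.
#'
#' @param x A data frame with the eight site-count columns.
#' @return `x` as a `tn_sites` tibble, invisibly unchanged otherwise.
#' @export
validate_site_counts <- function(x) {
  need <- c("chrom", "pos", "ref", "alt",
            "alt_tumor", "ref_tumor", "alt_normal", "ref_normal")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("site-counts table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  cnt <- c("alt_tumor", "ref_tumor", "alt_normal", "ref_normal")
  bad <- vapply(cnt, function(v) any(is.na(x[[v]]) | x[[v]] < 0), logical(1))
  if (any(bad)) {
    abort(paste0("negative or missing counts in: ",
                 paste(cnt[bad], collapse = ", ")))
  }
  if (any(is.na(x$pos) | x$pos < 1L)) abort("positions must be >= 1 (1-based)")
  if (any(x$ref == x$alt)) abort("ref and alt alleles must differ")
  x <- as_tibble(x)
  class(x) <- unique(c("tn_sites", class(x)))
  x
}

#' Canonicalize indel allele representation
#'
#' Trims bases shared between `ref` and `alt` (common suffix first, then common
#' prefix while keeping one anchor base), shifting `pos` right for every prefix
#' base removed. This collapses redundant VCF padding so that the same indel is
#' keyed identically for hotspot lookup regardless of how it was padded.
#' Full left-alignment across flanking reference sequence requires the
#' reference genome, which sits upstream of the count boundary.
#'
#' @param pos 1-based positions.
#' @param ref,alt Allele strings.
#' @return A tibble with columns `pos`, `ref`, `alt` (same length as input).
#' @examples
#' trim_alleles(100, "CAA", "CA")   # -> pos 100, C/CA -> "CA"/"C"
#' @export
trim_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos); ref <- toupper(ref); alt <- toupper(alt)
  out <- purrr::pmap(list(pos, ref, alt), function(p, r, a) {
    # drop shared trailing bases
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # drop shared leading bases, keep one anchor
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    list(p, r, a)
  })
  tibble(
    pos = vapply(out, function(z) z[[1]], integer(1)),
    ref = vapply(out, function(z) z[[2]], character(1)),
    alt = vapply(out, function(z) z[[3]], character(1))
  )
}

#' Read paired tumor/normal allele counts from VCF or TSV
#'
#' For VCF input the file must carry a per-sample `AD` (allele depth) FORMAT
#' field for exactly two samples; the tumor/normal identity of the two sample
#' columns is taken from the `tumor`/`normal` arguments and never guessed from
#' names (except for the package's own writer output, whose columns are named
#' `TUMOR` and `NORMAL`). Multiallelic records are decomposed into one row per
#' alternative allele. For TSV input the file must have the eight documented
#' columns of [site_counts()] (header required). Indel alleles are
#' canonicalized with [trim_alleles()] on read.
#'
#' @param path Path to a `.vcf` or tab-separated counts file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param tumor,normal Sample column names identifying tumor and normal in a
#'   VCF. Required unless the samples are literally `TUMOR`/`NORMAL`.
#' @return A `tn_sites` tibble (see [site_counts()]).
#' @export
read_site_counts <- function(path, format = c("auto", "vcf", "tsv"),
                             tumor = NULL, normal = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           pos = readr::col_integer(),
                           ref = readr::col_character(),
                           alt = readr::col_character(),
                           alt_tumor = readr::col_integer(),
                           ref_tumor = readr::col_integer(),
                           alt_normal = readr::col_integer(),
                           ref_normal = readr::col_integer()
                         ))
    x <- validate_site_counts(x)
  } else {
    x <- read_vcf_counts(path, tumor = tumor, normal = normal)
  }
  fix <- trim_alleles(x$pos, x$ref, x$alt)
  x$pos <- fix$pos; x$ref <- fix$ref; x$alt <- fix$alt
  validate_site_counts(x)
}

read_vcf_counts <- function(path, tumor = NULL, normal = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (length(samples) != 2L) {
    abort(paste0("expected exactly two samples (tumor, normal) in VCF, found ",
                 length(samples), ": ", paste(samples, collapse = ", ")))
  }
  if (is.null(tumor) || is.null(normal)) {
    if (setequal(samples, c("TUMOR", "NORMAL"))) {
      tumor <- "TUMOR"; normal <- "NORMAL"
    } else {
      abort("tumor/normal sample names must be given explicitly for this VCF")
    }
  }
  if (!all(c(tumor, normal) %in% samples)) {
    abort(paste0("samples ", tumor, "/", normal, " not found in VCF (has: ",
                 paste(samples, collapse = ", "), ")"))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || all(is.na(ad))) {
    abort("VCF has no per-sample AD (allele depth) field")
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad_t <- ad[i, tumor]; ad_n <- ad[i, normal]
    if (is.na(ad_t) || is.na(ad_n)) {
      abort(paste0("missing AD at record ", fix$CHROM[i], ":", fix$POS[i]))
    }
    dt <- suppressWarnings(as.integer(strsplit(ad_t, ",", fixed = TRUE)[[1]]))
    dn <- suppressWarnings(as.integer(strsplit(ad_n, ",", fixed = TRUE)[[1]]))
    if (length(dt) != length(alts) + 1L || length(dn) != length(alts) + 1L) {
      abort(paste0("AD arity does not match alleles at record ",
                   fix$CHROM[i], ":", fix$POS[i]))
    }
    tibble(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      alt_tumor = dt[-1L], ref_tumor = dt[1L],
      alt_normal = dn[-1L], ref_normal = dn[1L]
    )
  })
  validate_site_counts(dplyr::bind_rows(rows))
}

#' Read a hotspot site list
#'
#' Hotspots are recurrently mutated, clinically recognized sites that earn the
#' lower 1% reporting VAF threshold. The file is a 4-column TSV with header
#' `chrom pos ref alt` (1-based positions, one allele pair per row).
#'
#' @param path Path to the hotspot TSV.
#' @return A tibble of class `tn_hotspots`.
#' @export
read_hotspots <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         chrom = readr::col_character(),
                         pos = readr::col_integer(),
                         ref = readr::col_character(),
                         alt = readr::col_character()
                       ))
  hotspot_list(x$chrom, x$pos, x$ref, x$alt)
}

#' Construct a hotspot list in code
#'
#' @param chrom,pos,ref,alt Vectors defining hotspot sites (1-based positions).
#' @return A tibble of class `tn_hotspots` with canonicalized indel alleles.
#' @export
hotspot_list <- function(chrom = character(), pos = integer(),
                         ref = character(), alt = character()) {
  fix <- trim_alleles(as.integer(pos), as.character(ref), as.character(alt))
  x <- tibble(chrom = as.character(chrom), pos = fix$pos,
              ref = fix$ref, alt = fix$alt)
  class(x) <- unique(c("tn_hotspots", class(x)))
  x
}

#' Flag sites that are hotspots
#'
#' Membership is an exact (chrom, pos, ref, alt) key lookup on canonicalized
#' alleles; it decides which reporting VAF threshold the caller applies.
#'
#' @param sites A `tn_sites` (or calls) table.
#' @param hotspots A `tn_hotspots` table, or `NULL` for none.
#' @return Logical vector, one flag per row of `sites`.
#' @export
is_hotspot <- function(sites, hotspots) {
  if (is.null(hotspots) || nrow(hotspots) == 0L) {
    return(rep(FALSE, nrow(sites)))
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  key(sites) %in% key(hotspots)
}

## -- sortedness check shared by the VCF writer ------------------------------

is_sorted_calls <- function(chrom, pos) {
  if (length(chrom) <= 1L) return(TRUE)
  r <- rle(chrom)
  if (anyDuplicated(r$values) > 0L) return(FALSE)  # chrom blocks interleaved
  all(unlist(tapply(pos, factor(chrom, levels = r$values),
                    function(p) !is.unsorted(p), simplify = FALSE)))
}

fmt_num <- function(x) {
  ifelse(is.na(x), ".", sub("e([+-])0*(\\d)", "e\\1\\2", sprintf("%.6g", x)))
}

#' Write somatic calls to a two-sample VCF 4.2 file
#'
#' Emits one record per call with INFO keys `VAF_T`, `VAF_N`, `PVAL`, `QVAL`
#' and the `HOTSPOT` flag, `FILTER` set from the call's filter status, and a
#' per-sample `AD` FORMAT field (`TUMOR`, `NORMAL` columns) so the count fields
#' round-trip losslessly through [read_site_counts()].
#'
#' @param calls A `tn_calls` table from [call_somatic()], sorted by
#'   (chrom, pos). Unsorted input is an error, never silently sorted.
#' @param path Output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  if (nrow(calls) > 0L && !is_sorted_calls(calls$chrom, calls$pos)) {
    abort("calls must be sorted by (chrom, pos); refusing to sort silently")
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tnprofiler",
    "##INFO=<ID=VAF_T,Number=1,Type=Float,Description=\"Tumor variant allele fraction\">",
    "##INFO=<ID=VAF_N,Number=1,Type=Float,Description=\"Normal variant allele fraction\">",
    "##INFO=<ID=PVAL,Number=1,Type=Float,Description=\"One-sided Fisher exact p-value, tumor alt enrichment\">",
    "##INFO=<ID=QVAL,Number=1,Type=Float,Description=\"Benjamini-Hochberg adjusted p-value\">",
    "##INFO=<ID=HOTSPOT,Number=0,Type=Flag,Description=\"Site is on the hotspot list\">",
    "##FILTER=<ID=low_depth,Description=\"Below minimum tumor or normal depth\">",
    "##FILTER=<ID=not_significant,Description=\"Not rejected at the configured FDR\">",
    "##FILTER=<ID=below_vaf,Description=\"Significant but below the applicable VAF threshold\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref, alt)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL"
  )
  body <- character(0)
  if (nrow(calls) > 0L) {
    info <- paste0(
      "VAF_T=", fmt_num(calls$vaf_tumor),
      ";VAF_N=", fmt_num(calls$vaf_normal),
      ";PVAL=", fmt_num(calls$p_value),
      ifelse(is.na(calls$q_value), "", paste0(";QVAL=", fmt_num(calls$q_value))),
      ifelse(calls$is_hotspot, ";HOTSPOT", "")
    )
    body <- paste(
      calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
      calls$filter_status, info, "AD",
      paste0(calls$ref_tumor, ",", calls$alt_tumor),
      paste0(calls$ref_normal, ",", calls$alt_normal),
      sep = "\t"
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
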