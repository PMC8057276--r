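## classify a trimmed ref/alt pair: list(kind, seq) where seq is the inserted
## or deleted bases; kind "none" for substitutions
indel_seq_of <- function(ref, alt) {
  if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) {
    list(kind = "deletion", seq = substr(ref, nchar(alt) + 1L, nchar(ref)))
  } else if (nchar(alt) > nchar(ref) && startsWith(alt, ref)) {
    list(kind = "insertion", seq = substr(alt, nchar(ref) + 1L, nchar(alt)))
  } else {
    list(kind = "none", seq = "")
  }
}

#' Repeat context of one indel
#'
#' Finds the smallest unit u of length 1-3 bp such that the inserted/deleted
#' sequence is a whole number of copies of u, and counts the tandem copies of
#' u spanning the indel locus in the reference-plus-allele context (for a
#' deletion the reference window already contains the deleted copies; for an
#' insertion the inserted copies are spliced in before counting). A unit is
#' reported only when the context holds at least two in-phase copies - a lone
#' occurrence of the indel sequence is not a tandem run. Runs do not extend
#' past the window edges.
#'
#' @param ref,alt Anchored, trimmed allele strings (one a strict prefix of the
#'   other; see [trim_alleles()]).
#' @param window Reference sequence window covering the indel.
#' @param anchor 1-based position of `ref`'s first base within `window`.
#' @return `list(repeat_unit = <chr or NA>, unit_copies = <int>)`;
#'   `unit_copies` is 0 when no unit is found.
#' @examples
#' repeat_context("GA", "G", "CCGAAAAAGCC", anchor = 3)  # unit "A", 5 copies
#' @export
repeat_context <- function(ref, alt, window, anchor) {
  ref <- toupper(ref); alt <- toupper(alt); window <- toupper(window)
  anchor <- as.integer(anchor)
  ind <- indel_seq_of(ref, alt)
  if (ind$kind == "none") {
    abort("repeat scanning applies to indels only (got a substitution)")
  }
  if (anchor < 1L || anchor + nchar(ref) - 1L > nchar(window) ||
      substr(window, anchor, anchor + nchar(ref) - 1L) != ref) {
    abort("local reference window does not cover the indel's REF allele")
  }
  seq <- ind$seq
  len <- nchar(seq)
  shared <- if (ind$kind == "deletion") nchar(alt) else nchar(ref)
  if (ind$kind == "deletion") {
    ctx <- window
    i0 <- anchor + shared            # first deleted base, within window
  } else {
    at <- anchor + shared - 1L       # insert after this window position
    ctx <- paste0(substr(window, 1L, at), seq,
                  substr(window, at + 1L, nchar(window)))
    i0 <- at + 1L
  }
  nctx <- nchar(ctx)
  for (L in 1:3) {
    if (len %% L != 0L) next
    u <- substr(seq, 1L, L)
    if (strrep(u, len %/% L) != seq) next
    copies <- len %/% L
    j <- i0 - L
    while (j >= 1L && substr(ctx, j, j + L - 1L) == u) {
      copies <- copies + 1L
      j <- j - L
    }
    j <- i0 + len
    while (j + L - 1L <= nctx && substr(ctx, j, j + L - 1L) == u) {
      copies <- copies + 1L
      j <- j + L
    }
    if (copies >= 2L) {
      return(list(repeat_unit = u, unit_copies = as.integer(copies)))
    }
  }
  list(repeat_unit = NA_character_, unit_copies = 0L)
}

#' Annotate somatic indels with their tandem-repeat context
#'
#' Data-frame-first wrapper around [repeat_context()]: scans each tumor-specific
#' indel for mono-, di- or tri-nucleotide repeat structure. Substitution rows
#' are an error - only indels are scanned for microsatellite instability.
#'
#' @param indels A tibble with columns `ref`, `alt`, `local_reference` (the
#'   reference window) and `window_pos` (1-based position of the REF anchor
#'   base within the window). Calls from [call_somatic()] joined to windows
#'   satisfy this.
#' @return `indels` with `repeat_unit` (`NA` if none) and `unit_copies` added.
#' @export
annotate_repeat <- function(indels) {
  need <- c("ref", "alt", "local_reference", "window_pos")
  miss <- setdiff(need, names(indels))
  if (length(miss) > 0) {
    abort(paste0("indel table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  res <- purrr::pmap(
    list(indels$ref, indels$alt, indels$local_reference, indels$window_pos),
    repeat_context
  )
  indels |>
    mutate(
      repeat_unit = vapply(res, `[[`, character(1), "repeat_unit"),
      unit_copies = vapply(res, `[[`, integer(1), "unit_copies")
    )
}

#' Tally qualifying repeat-context indels
#'
#' Counts annotated indels sitting in a tandem run of at least
#' `min_unit_copies` copies of a 1-3 bp unit; this exome-wide tally is the MSI
#' statistic.
#'
#' @param indels Output of [annotate_repeat()] (needs `repeat_unit`,
#'   `unit_copies`), restricted by the caller to tumor-specific (PASS) indels.
#' @param min_unit_copies Minimum tandem copies for an indel to qualify.
#' @return Integer tally.
#' @export
msi_tally <- function(indels, min_unit_copies = 3L) {
  if (nrow(indels) == 0L) return(0L)
  sum(!is.na(indels$repeat_unit) & indels$unit_copies >= min_unit_copies)
}

#' Classify microsatellite instability status from the exome-wide tally
#'
#' A sample is microsatellite-instable-high (MSI-H) when its tally of
#' repeat-context tumor-specific indels is strictly above the cutoff
#' (default 6), otherwise microsatellite stable (MSS).
#'
#' @param tally Non-negative indel tally ([msi_tally()]).
#' @param cutoff Strict threshold; `tally > cutoff` declares MSI-H.
#' @return A list of class `tn_msi`: `tally`, `cutoff_used`, `status`.
#' @examples
#' classify_msi(7)$status  # "MSI-H"
#' classify_msi(6)$status  # "MSS": the cutoff itself is stable
#' @export
classify_msi <- function(tally, cutoff = 6L) {
  stopifnot(tally >= 0, cutoff >= 0)
  structure(
    list(tally = as.integer(tally), cutoff_used = as.integer(cutoff),
         status = if (tally > cutoff) "MSI-H" else "MSS"),
    class = "tn_msi"
  )
}

#' @export
print.tn_msi <- function(x, ...) {
  cat(sprintf("MSI status: %s (tally %d, cutoff %d)\n",
              x$status, x$tally, x$cutoff_used))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tn_msi <- function(x, ...) {
  tibble(tally = x$tally, cutoff = x$cutoff_used, status = x$status)
}
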