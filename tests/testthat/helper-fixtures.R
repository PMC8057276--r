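## small deterministic fixtures built in code

# target table with norm columns set directly (bypasses normalization) so
# gene/arm arithmetic can be checked exactly; log2 per target supplied
make_norm_targets <- function(genes, arms, log2_per_target, base = 1e5) {
  n <- length(log2_per_target)
  genes <- rep(genes, length.out = n)
  arms <- rep(arms, length.out = n)
  tibble::tibble(
    chrom = "chr1",
    start = (seq_len(n) - 1L) * 200L,
    end = (seq_len(n) - 1L) * 200L + 120L,
    gene = genes, arm = arms,
    gc_fraction = 0.5,
    raw_tumor = 1L, raw_normal = 1L,
    norm_tumor = base * 2^log2_per_target,
    norm_normal = base
  )
}

# a caller config with the reporting VAF filter disabled
config_no_vaf <- function(fdr = 0.01) {
  caller_config(fdr_level = fdr, vaf_min_hotspot = 0, vaf_min_other = 0)
}

# brute-force BH step-up rejection set (definition applied literally)
bh_brute_force <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- max(c(0L, which(ps <= seq_len(m) * fdr / m)))
  rej <- rep(FALSE, m)
  if (kmax > 0L) rej[o[seq_len(kmax)]] <- TRUE
  rej
}

# brute-force tandem-repeat scan: tries every unit length 1-3 and every
# in-phase run placement in the allele-bearing context
repeat_brute_force <- function(ref, alt, window, anchor) {
  del <- nchar(ref) > nchar(alt)
  seq <- if (del) substr(ref, nchar(alt) + 1L, nchar(ref))
  else substr(alt, nchar(ref) + 1L, nchar(alt))
  len <- nchar(seq)
  if (del) {
    ctx <- window
    i0 <- anchor + nchar(alt)
  } else {
    at <- anchor + nchar(ref) - 1L
    ctx <- paste0(substr(window, 1, at), seq, substr(window, at + 1, nchar(window)))
    i0 <- at + 1L
  }
  n <- nchar(ctx)
  for (L in 1:3) {
    if (len %% L != 0L) next
    u <- substr(seq, 1L, L)
    if (strrep(u, len %/% L) != seq) next
    best <- 0L
    for (s in seq_len(n - L + 1L)) {
      if ((s - i0) %% L != 0L) next              # must be in phase with the indel
      k <- 0L
      while (s + (k + 1L) * L - 1L <= n &&
             substr(ctx, s + k * L, s + (k + 1L) * L - 1L) == u) k <- k + 1L
      if (k >= 2L && s <= i0 && s + k * L >= i0 + len) best <- max(best, k)
    }
    if (best >= 2L) return(list(repeat_unit = u, unit_copies = best))
  }
  list(repeat_unit = NA_character_, unit_copies = 0L)
}

# Clopper-Pearson bounds by bisection on the binomial CDF (independent of the
# closed beta-quantile form used by the package)
cp_bisect <- function(x, n, level = 0.95) {
  a <- 1 - level
  root <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    root(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - a / 2, 0, 1)
  upper <- if (x == n) 1 else
    root(function(p) -(pbinom(x, n, p) - a / 2), 0, 1)
  list(ci_low = lower, ci_high = upper)
}
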