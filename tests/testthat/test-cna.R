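test_that("insert-size matching reweights onto the common envelope", {
  r <- match_insert_size(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r$weight_tumor, rep(1, 3))
  expect_equal(r$weight_normal, rep(1, 3))
  # tumor mass in a bin absent from the normal is zeroed
  r <- match_insert_size(c(10, 10), c(20, 0))
  expect_equal(r$weight_tumor[2], 0)
  # min/h rule, by hand: min = (2, 1)
  r <- match_insert_size(c(2, 2), c(3, 1))
  expect_equal(r$weight_tumor, c(1, 0.5))
  expect_equal(r$weight_normal, c(2 / 3, 1))
  expect_error(match_insert_size(c(1, 0), c(0, 4)), "disjoint")
})

test_that("normalization is invariant to library scale", {
  tr <- simulate_coverage_track(n_genes = 40, targets_per_gene = 5, seed = 101)
  a <- normalize_coverage(tr)
  tr2 <- dplyr::mutate(tr, raw_tumor = raw_tumor * 7L)
  b <- normalize_coverage(tr2)
  expect_equal(b$norm_tumor, a$norm_tumor, tolerance = 1e-10)
  expect_equal(b$norm_normal, a$norm_normal, tolerance = 1e-10)
  # and log2 ratios carry that invariance through the gene calls
  ga <- call_genes(a); gb <- call_genes(b)
  expect_equal(gb$log2_focal, ga$log2_focal, tolerance = 1e-10)
})

test_that("unbiased flat coverage is preserved up to global scaling", {
  tr <- simulate_coverage_track(n_genes = 40, targets_per_gene = 5,
                                dispersion = 0, seed = 102)
  nr <- normalize_coverage(tr)
  # with no bias to remove, normalization is close to a pure rescaling:
  # the per-target norm/raw factor is near-constant in each sample
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(nr$norm_tumor / nr$raw_tumor), 0.05)
  expect_lt(cv(nr$norm_normal / nr$raw_normal), 0.05)
  expect_lt(abs(mean(target_log2(nr)$log2_ratio)), 0.05)
})

test_that("simulated GC bias is removed by normalization", {
  tr <- simulate_coverage_track(
    n_genes = 100, targets_per_gene = 8, dispersion = 0.01,
    gc_bias = list(tumor = function(gc) exp(1.2 * (gc - 0.5)),
                   normal = function(gc) exp(-0.8 * (gc - 0.5))),
    seed = 103
  )
  lr <- target_log2(normalize_coverage(tr))
  expect_lt(abs(mean(lr$log2_ratio)), 0.1)
  # the residual GC trend is flattened: |cor(log2, gc)| small after correction
  raw_lr <- log2((tr$raw_tumor + 1) / (tr$raw_normal + 1))
  expect_gt(abs(cor(raw_lr, tr$gc_fraction)), 0.5)   # bias clearly present before
  expect_lt(abs(cor(lr$log2_ratio, lr$gc_fraction)), 0.15)
})

test_that("per-target log2 behaves at the limits", {
  t0 <- make_norm_targets(rep("G1", 3), rep("1p", 3), c(0, 0, 0))
  expect_equal(target_log2(t0)$log2_ratio, rep(0, 3))
  t1 <- make_norm_targets("G1", "1p", 1)      # tumor = 2x normal, 4 vs 2 copies
  expect_equal(target_log2(t1)$log2_ratio, 1, tolerance = 1e-4)
  tz <- make_norm_targets("G1", "1p", 0)
  tz$norm_tumor <- 0
  lr <- target_log2(tz)$log2_ratio
  expect_true(is.finite(lr) && lr < -10)
})

test_that("gene calls do arm-median arithmetic and thresholding", {
  # arm with background at +0.9 (arm-level gain) and one gene at +2.0
  genes <- c(rep(paste0("BG", 1:6), each = 3), rep("AMP1", 3))
  l2 <- c(rep(0.9, 18), rep(2.0, 3))
  calls <- call_genes(make_norm_targets(genes, "8q", l2))
  amp <- calls[calls$gene == "AMP1", ]
  expect_equal(amp$log2_arm, 0.9, tolerance = 1e-3)
  expect_equal(amp$log2_focal, 1.1, tolerance = 1e-3)
  expect_equal(amp$call, "amplification")
  # the arm-level gain itself is not called focally
  expect_true(all(calls$call[calls$gene != "AMP1"] == "neutral"))
  expect_equal(calls$log2_focal, calls$log2_gene - calls$log2_arm)
})

test_that("whole-arm shifts cancel and flat tracks stay neutral", {
  calls0 <- call_genes(make_norm_targets(rep(paste0("G", 1:5), each = 4),
                                         "3p", rep(0, 20)))
  expect_true(all(calls0$call == "neutral"))
  expect_equal(calls0$log2_focal, rep(0, 5))
  gain <- call_genes(make_norm_targets(rep(paste0("G", 1:5), each = 4),
                                       "3p", rep(1, 20)))
  expect_true(all(abs(gain$log2_focal) < 1e-6))
  expect_true(all(gain$call == "neutral"))
})

test_that("sparse genes are reported neutral with a low-evidence flag", {
  genes <- c(rep("BIG", 4), rep("TINY", 2), rep("PAD1", 3), rep("PAD2", 3))
  l2 <- c(rep(0, 4), rep(3, 2), rep(0, 6))   # TINY looks amplified but n=2
  calls <- call_genes(make_norm_targets(genes, "1q", l2))
  tiny <- calls[calls$gene == "TINY", ]
  expect_true(tiny$low_evidence)
  expect_equal(tiny$call, "neutral")
  expect_false(any(calls$low_evidence[calls$gene != "TINY"]))
})

test_that("a single outlier target cannot flip a five-target gene", {
  genes <- c(rep("G1", 5), rep("P1", 5), rep("P2", 5))
  l2 <- c(0, 0, 0, 0, 4, rep(0, 10))   # one wild target in a neutral gene
  calls <- call_genes(make_norm_targets(genes, "2p", l2))
  g1 <- calls[calls$gene == "G1", ]
  expect_equal(g1$call, "neutral")
})

test_that("doubling one gene's tumor counts is a local +1 log2 change", {
  tr <- simulate_coverage_track(n_genes = 60, targets_per_gene = 8, seed = 104)
  pick <- "GENE007"
  tr2 <- dplyr::mutate(tr, raw_tumor = ifelse(gene == pick,
                                              raw_tumor * 2L, raw_tumor))
  a <- call_genes(tr); b <- call_genes(tr2)
  d_gene <- b$log2_gene[b$gene == pick] - a$log2_gene[a$gene == pick]
  expect_lt(abs(d_gene - 1), 0.1)
  d_others <- abs(b$log2_focal[b$gene != pick] - a$log2_focal[a$gene != pick])
  expect_true(all(d_others < 0.1))
})

test_that("SEG-style output collapses targets per gene", {
  tr <- target_log2(make_norm_targets(rep(c("A1", "B1"), each = 3), "1p",
                                      c(0, 0, 0, 1, 1, 1)))
  out <- withr::local_tempfile(fileext = ".seg")
  write_seg(tr, out)
  seg <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(seg), 2L)
  expect_equal(sort(seg$n_targets), c(3L, 3L))
  expect_equal(seg$log2[seg$gene == "B1"], 1, tolerance = 1e-4)
})
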