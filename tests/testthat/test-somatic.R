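test_that("one-sided Fisher tail matches hand-enumerated tables", {
  # no alt reads anywhere: no evidence
  expect_equal(fisher_one_sided(0, 100, 0, 100), 1.0)
  # all 3 alt reads in the tumor given margins (3,3)/(3,3): C(3,3)C(3,0)/C(6,3)
  expect_equal(fisher_one_sided(3, 0, 0, 3), 1 / 20, tolerance = 1e-12)
  # tumor has no alt reads: P(X >= 0) = 1
  expect_equal(fisher_one_sided(0, 10, 5, 5), 1.0)
  expect_warning(fisher_one_sided(0, 0, 0, 0), "all-zero")
})

test_that("Fisher tail agrees with fisher.test on random tables", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.05, 1)))
    p_pkg <- suppressWarnings(
      fisher_one_sided(cells[1], cells[2], cells[3], cells[4]))
    m <- matrix(cells, nrow = 2, byrow = TRUE)  # rows tumor/normal, cols alt/ref
    p_ref <- stats::fisher.test(m, alternative = "greater")$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
})

test_that("p-value is monotone decreasing in tumor alt count", {
  set.seed(21)
  for (i in 1:50) {
    rt <- sample(0:300, 1); an <- sample(0:20, 1); rn <- sample(1:200, 1)
    p <- suppressWarnings(fisher_one_sided(0:40, rt, an, rn))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("BH step-up matches its definition on worked examples", {
  r <- bh_adjust(c(1, 1, 1), 0.01)
  expect_false(any(r$reject))
  # ranks 1,2 pass their step-up bounds at fdr 1%; 0.2 does not
  r <- bh_adjust(c(0.002, 0.003, 0.2), 0.01)
  expect_equal(r$reject, c(TRUE, TRUE, FALSE))
  r <- bh_adjust(0.5, 0.01)
  expect_equal(r$q_value, 0.5)
  expect_false(r$reject)
  expect_equal(nrow(bh_adjust(numeric(0))), 0L)
})

test_that("BH rejection set equals brute-force step-up on random vectors", {
  set.seed(31)
  for (i in 1:60) {
    m <- sample(1:200, 1)
    p <- round(runif(m), sample(c(1, 2, 5), 1))  # ties included
    fdr <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_adjust(p, fdr)$reject, bh_brute_force(p, fdr))
  }
})

test_that("caller assigns the documented filter statuses", {
  sites <- site_counts(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "C", alt = "T",
    #           signif vaf 3.75%   same, hotspot  germline-like   depth 0  clean somatic
    alt_tumor = c(15L,  15L,  200L, 0L, 120L),
    ref_tumor = c(385L, 385L, 200L, 0L, 280L),
    alt_normal = c(0L,  0L,   90L,  0L, 0L),
    ref_normal = c(180L, 180L, 90L, 0L, 180L)
  )
  hs <- hotspot_list("chr1", 200L, "C", "T")
  calls <- call_somatic(sites, hotspots = hs)
  expect_equal(nrow(calls), nrow(sites))
  # significant but 3.75% < 5%: filtered at a non-hotspot site...
  expect_equal(calls$filter_status[1], "below_vaf")
  # ...but reportable at a hotspot, where 1% applies
  expect_equal(calls$filter_status[2], "PASS")
  expect_true(calls$is_hotspot[2])
  # alt present equally in both samples: not somatic
  expect_equal(calls$filter_status[3], "not_significant")
  expect_equal(calls$filter_status[4], "low_depth")
  expect_equal(calls$p_value[4], 1.0)
  expect_true(is.na(calls$q_value[4]))
  expect_equal(calls$filter_status[5], "PASS")
  expect_equal(calls$vaf_tumor[5], 0.3)
  # statuses partition the call set
  expect_true(all(calls$filter_status %in%
                    c("PASS", "below_vaf", "not_significant", "low_depth")))
  g <- glance(calls)
  expect_equal(g$n_sites, 5L)
  expect_equal(g$n_pass, 2L)
})

test_that("normal-enriched sites are never PASS", {
  set.seed(41)
  for (i in 1:30) {
    an <- sample(5:50, 1)
    s <- site_counts("chr1", 1L, "A", "G",
                     alt_tumor = 0L, ref_tumor = 400L,
                     alt_normal = an, ref_normal = 180L - an)
    calls <- call_somatic(s, config = config_no_vaf())
    expect_false(calls$filter_status == "PASS")
  }
})

test_that("low-depth sites are excluded from the BH family", {
  s <- site_counts("chr1", c(1L, 2L), "A", "G",
                   alt_tumor = c(50L, 5L), ref_tumor = c(350L, 5L),
                   alt_normal = c(0L, 0L), ref_normal = c(180L, 2L))
  calls <- call_somatic(s)
  expect_equal(calls$filter_status[2], "low_depth")
  # the eligible site's q equals its p: a family of one
  expect_equal(calls$q_value[1], calls$p_value[1])
})
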