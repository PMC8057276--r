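test_that("TSV counts parse into a validated site table", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tpos\tref\talt\talt_tumor\tref_tumor\talt_normal\tref_normal",
    "chr7\t55249071\tC\tT\t40\t360\t0\t180",
    "chr1\t100\tG\tGA\t10\t390\t0\t180"
  ), tsv)
  x <- read_site_counts(tsv, format = "tsv")
  expect_s3_class(x, "tn_sites")
  expect_equal(nrow(x), 2L)
  expect_equal(x$alt_tumor[1], 40L)
  expect_equal(x$ref_tumor[1], 360L)
  expect_equal(x$alt_normal[1], 0L)
  expect_equal(x$ref_normal[1], 180L)
})

test_that("site-count invariants are enforced", {
  expect_error(site_counts("chr1", 1, "A", "A", 1, 1, 1, 1), "differ")
  expect_error(site_counts("chr1", 1, "A", "C", -1, 1, 1, 1), "negative")
  expect_error(site_counts("chr1", 0, "A", "C", 1, 1, 1, 1), "1-based")
  # zero-depth sites are allowed: they surface downstream as low_depth
  z <- site_counts("chr1", 5, "A", "C", 0, 0, 0, 0)
  expect_equal(z$alt_tumor + z$ref_tumor, 0L)
})

test_that("allele trimming canonicalizes padded indel representations", {
  # same deletion written three ways collapses to one key
  a <- trim_alleles(100, "CAA", "CA")
  b <- trim_alleles(99, "TCA", "TC")
  expect_equal(a$ref, "CA"); expect_equal(a$alt, "C"); expect_equal(a$pos, 100L)
  expect_equal(b$pos, 100L)  # prefix base dropped, position shifted right
  expect_equal(b$ref, "CA"); expect_equal(b$alt, "C")
  # SNVs and already-minimal alleles untouched
  expect_equal(trim_alleles(7, "G", "T"),
               tibble::tibble(pos = 7L, ref = "G", alt = "T"))
})

test_that("multiallelic VCF records decompose one row per alt allele", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL",
    "chr2\t500\t.\tA\tC,G\t.\t.\t.\tAD\t300,40,10\t180,0,1",
    "chr2\t900\t.\tT\tTA\t.\t.\t.\tAD\t350,30\t170,0"
  ), vcf)
  x <- read_site_counts(vcf, tumor = "TUMOR", normal = "NORMAL")
  expect_equal(nrow(x), 3L)  # 2 alts + 1 alt
  expect_equal(x$pos[1:2], c(500L, 500L))
  expect_equal(x$alt[1:2], c("C", "G"))
  expect_equal(x$alt_tumor[1:2], c(40L, 10L))
  expect_equal(x$ref_tumor[1:2], c(300L, 300L))
  expect_equal(x$alt_normal[1:2], c(0L, 1L))
})

test_that("VCF reading rejects bad sample setups and missing AD", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t10\t.\tA\tC\t.\t.\t.\tGT\t0/1\t0/0\t0/0"
  ), vcf)
  expect_error(read_site_counts(vcf, tumor = "S1", normal = "S2"),
               "exactly two samples")
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t10\t.\tA\tC\t.\t.\t.\tGT\t0/1\t0/0"
  ), vcf2)
  expect_error(read_site_counts(vcf2, tumor = "S1", normal = "S2"), "AD")
  # sample identity is never guessed from arbitrary names
  vcf3 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "chr1\t10\t.\tA\tC\t.\t.\t.\tAD\t10,5\t20,0"
  ), vcf3)
  expect_error(read_site_counts(vcf3), "explicitly")
  ok <- read_site_counts(vcf3, tumor = "S2", normal = "S1")
  expect_equal(ok$alt_tumor, 0L)
  expect_equal(ok$alt_normal, 5L)
})

test_that("calls VCF round-trips counts losslessly and refuses unsorted input", {
  sites <- site_counts(
    chrom = c("chr1", "chr1", "chr2"), pos = c(100L, 250L, 50L),
    ref = c("C", "G", "AT"), alt = c("T", "GA", "A"),
    alt_tumor = c(120L, 30L, 0L), ref_tumor = c(280L, 370L, 400L),
    alt_normal = c(1L, 0L, 0L), ref_normal = c(180L, 179L, 181L)
  )
  calls <- call_somatic(sites, hotspots = hotspot_list("chr1", 100L, "C", "T"))
  out <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls, out)
  back <- read_site_counts(out)
  for (col in c("chrom", "pos", "ref", "alt",
                "alt_tumor", "ref_tumor", "alt_normal", "ref_normal")) {
    expect_equal(back[[col]], sites[[col]], info = col)
  }
  expect_error(write_calls_vcf(calls[c(2, 1, 3), ], out), "sorted")
  # header-only file for an empty call set still parses
  write_calls_vcf(calls[0, ], out)
  expect_equal(length(readLines(out)), 12L)
})
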