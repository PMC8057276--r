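---
title: "Methods: paired tumor-normal somatic profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired tumor-normal somatic profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnprofiler)
library(dplyr)
```

tnprofiler implements the analytic core of a paired tumor-normal
comprehensive genomic profiling assay: somatic SNV/indel calling by
germline subtraction, focal copy-number calling from normalized coverage
ratios, exome-wide microsatellite-instability (MSI) classification, and
tumor mutational burden (TMB) scoring, together with a synthetic-data
generator and a validation harness. This vignette is the package's account
of the statistics it implements, the parameters that matter, and the
choices made where the design was genuinely open.

## Somatic calling by tumor-normal subtraction

The input boundary is a table of per-site haplotype counts: alt and ref
read counts in the tumor and in the matched normal. Upstream haplotype
extraction (alignment, base-quality filtering, local assembly) is out of
scope; counts are accepted as given.

For each site the four counts form a 2x2 contingency table and a one-sided
Fisher's exact test asks whether the alternative haplotype is enriched in
the tumor relative to the germline. Conditional on the margins, the tumor
alt count is hypergeometric, and the p-value is the exact upper tail
$P(X \ge x_\text{alt,tumor})$, computed vectorized via `phyper()`. The
one-sided direction is fixed: a variant enriched in the *normal* can never
be called somatic.

All sites passing the depth minima (240x tumor, 100x normal by default)
form a single Benjamini-Hochberg family per sample, tested at a 1% false
discovery rate. Sites failing the depth minima are reported `low_depth`
and excluded from the family, so uninformative tables do not dilute the
step-up rank. Rejected sites are then screened by reporting
variant-allele-fraction (VAF) thresholds: 1% at hotspot sites (exact
chrom/pos/ref/alt lookup on canonicalized alleles), 5% elsewhere. The
thresholds act after significance because the caller's role is somatic
classification; the VAF screen is a reporting filter.

Two properties worth stating:

* Fisher's test on discrete counts is conservative, so the realized false
  discovery proportion sits well below the nominal 1% (typically at or
  near zero under the simulation conditions below).
* Allele representations are canonicalized on read by trimming shared
  suffix/prefix bases (keeping the anchor base and shifting the position),
  so padded VCF spellings of the same indel key identically for hotspot
  lookup. Full left-alignment across flanking reference sequence would
  need the reference genome, which sits upstream of the count boundary.

## Focal copy number

Per-target tumor and normal coverage is normalized independently per
sample in three steps:

1. **Library size** - counts per million, making every downstream
   quantity invariant to sequencing throughput.
2. **GC content** - targets are split into 20 GC quantile bins and each
   target is divided by its bin's median relative to the global median.
   Binned medians are monotone-safe and need no functional form for the
   capture-efficiency curve.
3. **Dinucleotide composition** - a robust linear fit (`MASS::rlm`) of
   log-coverage residuals on the 16 dinucleotide fractions (one dropped:
   compositions sum to 1) is subtracted after centering. This targets the
   fragmentation bias of FFPE libraries; the robust loss keeps true focal
   events from leveraging the fit.

Insert-size matching is available as explicit per-fragment weights that
reweight both samples' fragment-length histograms onto their common
envelope `min(h_t, h_n)`; it operates on histograms supplied by the user,
since fragment lengths live in the alignments, upstream of this package.

Each target then gets `log2((norm_t + c) / (norm_n + c))` with pseudocount
`c = 1` guarding zeros (normalized values are kept on the counts-per-
million scale, so the pseudocount is negligible for covered targets). The
gene statistic `log2_gene` is the median over the gene's targets; the arm
statistic `log2_arm` is the median over all targets on the gene's
chromosome arm; their difference `log2_focal` separates focal events from
arm-level and ploidy shifts (a whole-arm gain cancels exactly). Medians
throughout mean a single outlier target cannot flip a five-target gene.

**Call thresholds.** In a pure diploid tumor the minimal reportable
amplification - a 4-copy gain - sits at `log2 = 1`, and single-copy loss
at `log2 = -1`. A decision boundary placed exactly on the class value
would classify the minimal event at coin-flip rates under sampling noise,
so the defaults are the midpoints that separate the minimal reportable
state from the nearest non-reportable one: amplification at `+0.75`
(between a 3-copy gain, 0.585, and a 4-copy gain, 1.0) and deletion at
`-0.5` (between neutral and single-copy loss). Both are configuration,
not constants. Tumor purity is not modeled: with lower tumor content all
ratios shrink toward zero and the thresholds become conservative; that
behavior is intended and documented rather than corrected.

Genes with fewer than 3 targets are reported neutral with a
`low_evidence` flag rather than dropped, so output is complete per gene.

## MSI classification

MSI status is estimated exome-wide from tumor-specific (PASS) indels: each
indel is scanned for mono-, di- or tri-nucleotide repeat structure, and
the sample is MSI-high when strictly more than six qualifying indels are
found; otherwise it is microsatellite stable.

An indel *qualifies* when (a) its inserted/deleted sequence is a whole
number of copies of the smallest unit u with `1 <= |u| <= 3`, and (b) the
locus sits in a tandem run of at least three in-phase copies of u in the
reference-plus-allele context (for deletions the deleted copies are
already in the reference window; for insertions the inserted copies are
spliced in before counting). Three readings in this definition were open
and are resolved as follows:

* "at least three" counts tandem **unit copies**, not base pairs - a
  base-pair reading would qualify every trinucleotide event trivially.
* A unit is only reported when the context holds at least two in-phase
  copies; a lone occurrence of the indel sequence is not a microsatellite.
* Partial-unit indels (e.g. a 3-bp deletion out of a dinucleotide run) do
  not qualify: requiring whole unit copies is deterministic and
  conservative.

Runs are detected within a +/-20 bp window and do not cross its edges;
interrupted (impure) runs are not bridged. The cutoff ("above six") is
strict: a tally of exactly 6 is stable. Both the copy minimum and the
cutoff are arguments.

## TMB

TMB is the number of coding somatic alterations per megabase of target
space: PASS calls whose position falls in a coding interval, divided by
the coding space in Mb (taken from the merged interval length when not
given). All PASS classes count, synonymous included - the caller makes no
consequence prediction, and the assay's defining feature is that germline
subtraction, not database filtering, removes the germline background.
The printed category ranges leave gaps at 5-6 and 19-20 mut/Mb; they are
closed as `Low < 5 <= Intermediate < 20 <= High`, so the three classes
partition the non-negative line; both boundaries are configurable. The
denominator is coding-only space, matching the numerator's definition.

## Run-level QC

`qc_gate()` applies the assay's run-level criteria: mean depth >= 240x
tumor / 100x normal, >= 90% of targeted bases at 40x (gated per sample),
Q30 >= 80%, and for runs with RNA >= 100 million reads with >= 50%
aligned. Q30 and RNA numbers are accepted as sequencer-side metrics; a
FASTQ Q30 helper exists for synthetic tests only. The gate is monotone:
improving any metric can never turn a pass into a fail.

## The synthetic-data generator

The generator exists so every stage is testable without any external data,
and its defaults are the study conditions the analysis is validated under:

* **Paired counts** - Poisson depths around 400x tumor / 180x normal,
  binomial alt counts: true VAF at somatic sites (tumor only), 0.5 at
  germline hets (both samples), and a 0.2% error rate at null sites -
  low enough that the null VAF sits well below the 1% hotspot threshold.
  This is the minimal model consistent with the assay's depth statements;
  it has no strand, mapping or FFPE-deamination structure.
* **Dilution series** - 1:1 serial dilutions down to 1:64 halve the
  expected VAF per step; each replicate of each step is sequenced as one
  site and analyzed as its own single-site family.
* **Coverage tracks** - negative binomial counts with mean proportional
  to `copy/2 x gc_bias x dinuc_bias x depth`. Defaults: 8 targets per
  gene (a typical exon count per captured gene) and dispersion 0.02
  (moderate FFPE overdispersion; variance `mu + 0.02 mu^2`).
* **Repeat-context indels** - planted units of length 1-3 (mix
  0.6/0.25/0.15), 3-8 tandem copies, rejection-sampled so flanks neither
  extend nor rephase the planted run; non-repeat indels are
  rejection-sampled to not qualify. The planted tally is therefore exact
  truth for the annotator.

All generators are seed-deterministic. What passing tests on this
generator do **not** show: robustness to mapping artifacts, strand bias,
FFPE damage signatures, impure repeat runs, or contaminated normals -
none of which the generator emulates.

## Problem sizes and numerical choices

The test suite verifies the Fisher tail against exhaustive hypergeometric
enumeration on *all* 2x2 tables with total N <= 50 (tolerance 1e-12), BH
rejection sets against the brute-force step-up definition on 1,000 random
p-vectors, and Clopper-Pearson intervals against a binomial-CDF bisection
oracle. FDR control is measured on 20 replicates of 20,000 sites (19,000
nulls, 1,000 somatic at VAF 0.10-0.30), the same conditions
`scripts/acceptance.R` recomputes; copy-state recovery uses 120 genes x 8
targets with states {0, 1, 2, 4, 8}. These sizes give stable Monte-Carlo
estimates while keeping the whole suite fast on one CPU.

Confidence intervals are exact Clopper-Pearson (closed beta-quantile
form) - the conservative default when the interval method is otherwise
unspecified; the `method` field records it so alternatives can be added.
Percentages print to one decimal. BH ties break by stable input order;
q-values are reported for non-rejected sites too.

## Known limitations

* **Count-level detection floor.** A one-sided Fisher test at 400x/180x
  needs roughly 13 tumor alt reads (with a clean normal) to reach
  p <= 0.01, so the count-level caller's measured dilution LOD is ~8%
  expected VAF (per-step detection under the packaged dilution
  conditions: 100% at >= 8%, 75% at 4%, 5% at 2%, 0% at 1%).
  Reliable sub-percent hotspot detection in a production assay comes from
  base-quality-aware evidence in the upstream haplotype caller, which is
  outside this package's count boundary. The 1% and 5% reporting
  thresholds are implemented as specified, but users should not expect
  the Fisher stage alone to *discover* variants below ~5% VAF at these
  depths - notably, that floor coincides with the assay's non-hotspot
  reporting threshold.
* The BH family excludes sites failing depth minima; including them would
  only make the procedure more conservative, but the choice matters for
  q-value comparability across samples.
* No purity/ploidy estimation, no allele-specific copy number, no
  B-allele-frequency integration; arm adjustment handles ploidy only to
  first order.
* MSI run detection is window-bounded (+/-20 bp) and phase-strict;
  very long runs and interrupted runs are under-counted.
* `vaf_tumor` is defined as 0 at zero depth so the column is total; such
  sites are always `low_depth`.

## A worked example

```{r example}
set.seed(1)
sites <- simulate_paired_counts(5000, somatic_fraction = 0.02,
                                germline_fraction = 0.05, seed = 7)
calls <- call_somatic(sites)
glance(calls)
score_calls(calls)[c("tp", "fp", "fn")]
```

```{r cna}
tr <- simulate_coverage_track(n_genes = 60, copy_states = c(GENE010 = 8),
                              seed = 11)
subset(call_genes(tr), call != "neutral")
```
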