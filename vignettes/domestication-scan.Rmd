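---
title: "Detecting domestication sweeps in inbred mouse panels"
author: "DomestiScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domestication sweeps in inbred mouse panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DomestiScan)
```

# The problem

Classical inbred mouse strains are fully homozygous mosaics of a few
wild founder genomes, shaped by a founder bottleneck, inbreeding, drift
— and artificial selection for laboratory traits such as tameness.
Bottleneck and drift depress diversity *everywhere*; selection depresses
it *locally*, dragging linked variation to fixation (hitchhiking). No
single statistic separates the two reliably, so DomestiScan follows the
standard multi-evidence design: three statistics with different error
modes are ranked independently and only their intersection is reported.
A gene must sit in a top-5% window of the π ratio **and** of Fst **and**
of XP-CLR to be called a positively selected gene (PSG). Drift creates
sharp allele-frequency excursions at scattered sites; it rarely creates
coincident extremes of all three windowed statistics at the same locus.

# Data model

Genotypes live in a `GenotypePanel`: two sites × samples integer
matrices of allele indices (unphased, ploidy 2, `NA` = missing), a
`GRanges` site table (1-based VCF positions, REF/ALT metadata), and a
group factor (`wild` vs `classical_inbred`). VCF is read through
`VariantAnnotation` and written as minimal GT-only VCF 4.2; gene models
(span + exons) round-trip through BED12 via `rtracklayer`. All interval
arithmetic is half-open 0-based internally and 1-based at the VCF/report
boundary.

Site filters reproduce the usual scan hygiene: bi-allelic SNPs only and
missing-genotype fraction strictly below 0.1, computed over the merged
sample set (the filter precedes the group split, so per-group filtering
would change the denominator semantics).

# The scan

**Windows.** 40 kb windows advancing by 20 kb, anchored at 0 per
chromosome; start positions continue while `start + step <= length`, so
every interior bp is covered by exactly size/step windows. Truncated
trailing windows are emitted but flagged and masked from ranking, as are
windows with fewer than `min_snps` (default 10) SNPs — with ~1 SNP per
100 bp in the fixture, a 40 kb window holds ~400 SNPs, so the mask only
fires on genuinely information-poor windows.

**π ratio.** Site heterozygosity uses the unbiased estimator
h = n/(n−1)(1 − Σp²) over called alleles (equal to the mean pairwise
haplotype difference, which is how the tests verify it), summed per
window and divided by window length. For the ratio, fixation in the
inbred panel with retained wild diversity is the strongest possible
signal, so π_inbred = 0 maps to an +Inf sentinel that ranks first;
windows with both diversities zero are masked for this statistic. Window
boundaries are half-open; a site on the start belongs to the window, one
on the end does not.

**Fst.** The two-population ANOVA estimator on allele counts (mean
squares among/within populations with the n_c sample-size correction).
Raw site values are kept — negatives are informative about the
within-group variance and clipping would bias window means upward — and
the window statistic is their arithmetic mean (the ratio-of-sums
alternative weights SNPs differently; with dense windows the two are
close, and the mean keeps masked-site bookkeeping trivial).

**XP-CLR.** A deliberately simplified composite likelihood in the
cross-population family. Per site, with wild as reference (selection
acted on the inbred lineage): the reference frequency p₁ (clamped to
[1/2n₁, 1−1/2n₁]) seeds a truncated-normal drift law
q ~ N(p₁, ω p₁(1−p₁)) with the out-of-range mass as point masses at the
boundaries; the neutral likelihood integrates the object binomial over
that law on a 200-cell grid. Under the sweep model the site escapes
hitchhiking with probability c = 1 − exp(−d/θ) (d = distance to the
window center) and otherwise fixes on the favoured background (mass p₁
at 1, 1−p₁ at 0). Because a boundary start drifts nowhere, the selected
likelihood reduces to c·L₀ + (1−c)(p₁[m₂=n₂] + (1−p₁)[m₂=0]), which
makes the model exactly nested at c → 1: the window score
CLR = max(0, 2·max_θ Σ(log L₁ − log L₀)) is non-negative by
construction. The sweep position is fixed at the window center and θ is
maximised over 15 log-spaced values from 10² to 10⁷ bp; there is no
LD-based SNP down-weighting. Scores are therefore comparable within a
run, not to other implementations. Sites that yield a non-finite
likelihood (an unfixed object allele exactly at the window center, where
c = 0) are skipped with a warning rather than propagating −Inf.

**ω calibration.** The drift scale is set from the data as
ω = F̄/(1−F̄), with F̄ the genome-wide mean of positive site Fst values
clamped to [10⁻³, 0.99]. For extremely bottlenecked panels this formula
can exceed the admissible parameter range, so the `XpclrParams`
constructor caps ω at 9.99; on the fixture ω ≈ 0.1.

**Ranking and intersection.** Each statistic selects
ceiling(0.05 × unmasked) windows, ties broken deterministically by
(statistic, chromosome, start). Genes enter a statistic's set on ≥ 1 bp
span overlap with any selected window (gene spans, not transcript
bodies, since the annotation model is span + exons), once per statistic
(set semantics). PSGs are the sorted three-way intersection; Venn counts
are reported alongside.

# The synthetic study

The generator emulates the statistical structure the scan assumes, not
mouse demography — there is no coalescent. Per-site derived-allele
frequencies are drawn i.i.d. from the neutral SFS weight 1/i (exponent
configurable) over allele counts i, and wild genotypes are binomial
draws; the analytic mean of 2p(1−p) under that law is the oracle for the
simulator's own tests. Linkage exists only where the scan needs it: each
inbred strain is a homozygous mosaic of 8 founder haplotypes (taken from
wild samples) with exponentially distributed blocks of mean 100 kb, so
the inbred panel carries the founder bottleneck genome-wide.

Sweeps are planted with the same escape geometry the XP-CLR model
assumes: inside a declared region, every (site, strain) pair carries one
shared founder haplotype except with probability 1 − exp(−d/half_width)
of escaping to the strain's own mosaic. Because a 40 kb window centered
on the sweep retains roughly 1.13 × mean(escape) of baseline diversity,
the escape scale must be much larger than the window for the core to
lose essentially all diversity: the fixture uses half_width = 300 kb,
under which the core windows keep < 10% of background π while the flanks
grade smoothly back to neutral. The truth table therefore distinguishes
the *swept core* (windows containing a sweep center, and the genes
overlapping them — these must be recovered) from the wider *region*
(partially swept; excluded from "non-sweep" comparisons, since its
windows are neither clean sweeps nor clean nulls).

Default study conditions (the documented fixture, seed 1729): 2
chromosomes × 2 Mb, 20,000 SNPs, 20 wild + 20 inbred samples, 8
founders, 100 genes of 20 kb on a 40 kb grid, 3 sweeps centered on gene
midpoints (chr1:500k, chr1:1.3M, chr2:980k), 1% missing genotypes, 0.2%
residual inbred heterozygosity. These sizes keep a full scan (including
XP-CLR) under ~10 s on one CPU while leaving ~200 sites per window and
~100 clean null windows for percentile comparisons. Expression fixtures
are log-normal RPKM over 28 tissues (collapsing to the 17 standard
categories), with a designated gene set multiplied by 4 in the six
brain-related columns; DE tables, phenotype flags and Ct tables follow
the same designated-set enrichment logic.

What passing recovery tests does — and does not — show: the scan
reliably recovers hard, isolated sweeps in a panel whose background
matches the model's assumptions (i.i.d. frequencies, no population
structure within groups, uniform SNP density). Real mouse panels add
subspecies admixture, LD beyond founder mosaics, variable mutation and
recombination rates, and reference bias; the fixture makes no claim
about power under those conditions.

# Downstream arithmetic

* **Tissue categories.** Embryonic CNS tissues merge into *immature
  brain*; cerebellum/cortex/frontal lobe into *brain*; embryonic livers,
  gut segments, spleen+thymus and the fat pads into their categories;
  every other tissue is a singleton — 17 categories in all, merged by
  arithmetic mean. A gene is *highly expressed* in a category at ≥ 2 ×
  its own cross-category mean (inclusive threshold; an all-zero gene is
  never flagged, and no gene can be flagged in more than 8 of 17
  categories). Reported percentages round half-up to one decimal.
* **Rank-sum.** Brain vs other categories, Mann–Whitney U with the
  tie-corrected normal approximation, one-sided ("brain greater") since
  the question is directional; no multiple-testing correction is applied
  because raw counts, not a significant-gene list, are reported. An
  all-tied row carries no evidence and is flagged with p = 0.5.
* **DE elevation.** A gene is differentially expressed at padj < 0.05
  and FPKM > 1 (both strict; the FPKM is the larger of the two group
  means, the natural "expressed in the tissue" reading). Per tissue the
  DE fraction among PSGs is compared with the genome-wide fraction as a
  percentage-point delta and a fold.
* **Candidate rules.** The strict rule demands reference homozygosity in
  *no* wild sample and in *every* inbred sample; any missing genotype
  disqualifies the site (conservative and reproducible — imputing would
  manufacture candidates). The relaxed rule passes when the wild
  reference frequency is strictly below 20% of the inbred one, with
  frequencies computed over called allele copies (not per strain).
  Allelicity counts distinct observed alleles per group
  (single/bi/tri).
* **qPCR.** Replicate wells average in Ct space; ΔΔCt centers on the
  arithmetic control-group mean of ΔCt, so the *geometric* mean of
  control folds is exactly 1. Folds are invariant to global Ct shifts
  and invert when target and reference swap — both held to machine
  precision in the tests.

# Clustering check

The wild/inbred separation is verified with an allele-sharing distance
(mean of 1 − shared-allele fraction over co-called sites; 0, ½ or 1 per
site) and a from-scratch Saitou–Nei neighbor joining with two
determinism guarantees: Q-matrix ties break on the smallest (i, j) index
pair, and negative branch lengths clamp to 0 with a warning. On additive
matrices the tree reproduces the input distances exactly (the test
round-trips path lengths to 1e−9 and cross-checks the topology against
`ape::nj`); on the fixture the inbred samples form their own clade.
Bootstrap support is out of scope — a single tree suffices for a
separation check.

# Numerical choices and degenerate inputs

* Percent reporting uses round-half-up to one decimal (base R's
  round-half-even would report 38.85 → 38.8 vs the conventional 38.9).
* `selectTopWindows` uses ceiling counts (41 unmasked windows → 3
  selected) and is total-order deterministic including +Inf sentinels.
* Sites with fewer than 2 called alleles in a group contribute h = 0
  and are flagged; Fst is undefined (site skipped) when both groups are
  monomorphic or either has < 2 called alleles.
* An empty window is π = 0 under per-bp summation but undefined (masked)
  under the mean mode used for Fst.
* All generators are pure functions of (configuration, seed); the RNG
  state of the caller is saved and restored.

# Limitations

The XP-CLR variant fixes the sweep at the window center and ignores LD
weighting, trading power for testability; scores should be ranked, not
interpreted on the original program's scale. The π-ratio sentinel makes
fixed windows incomparable among themselves (they tie and fall back on
coordinate order). The gene annotation model is span + exons only, so
UTR/splice-level site classes collapse into exonic/intronic/intergenic.
The generator's i.i.d. frequency model understates the variance of
windowed statistics relative to data with real LD, which makes the
fixture's top-5% thresholds cleaner than they would be on resequencing
panels.
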