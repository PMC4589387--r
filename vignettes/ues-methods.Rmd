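---
title: "Matched Monte Carlo enrichment testing of GWAS risk SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched Monte Carlo enrichment testing of GWAS risk SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ues)
```

## The question and the statistic

Most GWAS-identified risk variants are non-coding, and the reported SNP is
often only a tag for the functional variant it is correlated with. This
package asks a set-level question: do a disease's risk SNPs — or any of
their linkage-disequilibrium (LD) partners — fall inside a genomic
annotation (open chromatin, enhancer states, ChIP-Seq peaks) more often
than comparable random SNPs would?

The statistic is a **collapsed locus count**. Each index SNP is expanded
into a locus: the SNP itself plus every partner with $r^2$ above a
threshold (0.8 by default, with 0.2/0.4/0.6/1 as sensitivity settings; the
comparator is strict below 1 and equality at 1). A locus *hits* a track
when any member's position lies inside an interval, and hitting loci whose
member sets intersect are merged into connected components, so one
physical region tagged by several reported SNPs is counted once. The
observed count $o$ is compared to the same statistic on $n$ random SNP
sets via the empirical exceedance p-value

$$ p = \frac{r}{n}, \qquad r = \#\{\text{null sets with count} \ge o\}, $$

reported as the bound $p < 1/n$ when $r = 0$ (an empirical zero is never a
zero probability). Across $T$ tracks, significance is declared at the
Bonferroni level $\alpha/T$.

## The matched null

Random sets are not uniform draws. SNP arrays are biased with respect to
genomic features, and both distance to genes and local LD strongly shape
overlap probabilities. Each null set is therefore drawn from the
genotyping-platform catalog so that it reproduces the input set's joint
distribution over two axes:

* **distance to the nearest transcription start site**, and
* **number of LD partners** at the active threshold.

Quartile edges for each axis are computed from the input SNPs (type-7
linear interpolation; a value equal to an edge falls into the lower bin,
making assignment total and deterministic), giving a $4 \times 4$ grid.
Every matched set reproduces the input's per-bin counts *exactly* — this
is asserted in the tests, not sampled. Sampling is without replacement
within a set (a SNP set with duplicates is meaningless for locus
counting) and independent across sets; each set has its own RNG substream
derived from the master seed, so runs are reproducible and
order-independent. Input SNPs are not removed from the sampling frame;
with $10^4$ sets from a platform of thousands of SNPs their presence
perturbs the null negligibly.

The platform frame is curated before sampling: the extended HLA region
(chr6:29,570,005–33,377,658, build 37) is excluded for its extreme LD,
variants sharing a start position are dropped entirely (both copies — the
records are ambiguous), and only variants with MAF $\ge$ 5% are retained,
mirroring standard GWAS quality filters. The input list is curated by HLA
exclusion and LD-independence pruning: correlated variants ($r^2 > 0.8$)
are clumped greedily by ascending GWAS p-value, keeping the most
significant member (ties break to the smaller rsID). An optional location
prune additionally enforces a minimum pairwise separation (1 Mb by
default, strict inequality: two SNPs exactly 1 Mb apart coexist), again
greedy by significance. Greedy-by-significance is the standard clumping
convention; the pairwise rule alone does not determine the outcome for
groups larger than two, so the convention is documented and tested rather
than assumed.

All tracks in one run are tested against byte-identical null sets, so
per-track results are directly comparable. Tracks are normalized on
reading: intervals are sorted and overlapping *or abutting* intervals
merged. Merging abutting intervals cannot change any per-variant overlap
call (the covered-base set is untouched) and makes interval counts
canonical. Variants use 1-based positions, BED intervals 0-based
half-open; both become 1-based closed `GRanges` at parse time, so a
variant at position $p$ hits $[s, e)$ iff $s < p \le e$ in BED terms.

## The locus-local shift test

The matched-SNP null answers "are these SNPs unusual among platform
SNPs?". A complementary null asks "within each risk locus, is the
annotation unusually close to the variants?". For each locus (index SNP
plus $r^2 > 0.8$ partners) the boundaries run from the outermost member
positions, extended on each side by **twice the median interval length**
of the tested annotation and clipped at the chromosome start. The locus
is circularized; in each of 10,000 iterations every locus independently
draws a uniform integer offset in $[0, L)$, its clipped annotations rotate
by that offset, and the number of loci with any member inside a shifted
annotation is recorded. The p-value is the fraction of iterations whose
count reaches the observed one (the inclusive comparator matches the
exceedance rule above; a strict variant is available via a flag).
Annotations straddling a boundary are clipped to the locus first, which is
what makes the rotation well defined; local annotation density is
preserved exactly. For a single locus with a single member, enumeration
of all $L$ offsets shows the null overlap probability is exactly the
covered fraction of the circularized locus — the test suite checks the
Monte Carlo estimate against this closed form.

## The synthetic study generator

Real inputs (consortium annotation tracks, reference-panel LD, platform
manifests) are large external downloads, so validation runs on generated
studies that emulate all five inputs. The defaults describe one fixed,
scaled-down human-like condition:

| parameter | default | rationale |
|---|---|---|
| genome | 2 × 10 Mb | two chromosomes exercise per-chromosome logic |
| platform SNPs | 6,000 | ~1 per 3.3 kb, typical array density |
| LD blocks | 20 kb, $r^2 = 0.9$ within, 0 between | human-scale blocks; all-or-nothing LD keeps partner counts and the analytic null tractable |
| TSS | 200 | ~1 per 100 kb |
| track | 300-bp intervals, 3% coverage | DNase-peak-sized features |
| input SNPs | 30 | the scale of a curated risk-SNP list |
| MAF | uniform on [0.05, 0.5] | platform frame is already MAF-filtered |

Positions are uniform and unique; the track is assembled from fixed-size
windows sampled without replacement, so realized coverage matches the
target to rounding (verified to 1% relative). `plantedFraction` of the
input SNPs are forced to overlap the track — either the SNP itself
(`"index"` mode) or, in `"partner"` mode, a same-block LD partner while
the index SNP stays outside, exercising the tag-SNP detection path where
the reported variant misses the annotation but its proxy hits. All
randomness derives from one seed through named substreams; identical
configurations produce byte-identical studies.

Because within-block LD is all-or-nothing, a matched set's collapsed
count has a closed form: it is the number of distinct sampled blocks
containing a track-overlapping SNP, and the probability a block goes
unsampled factorizes hypergeometrically over bins
(`expectedMatchedNullMean()`). The simpler per-locus form
$\sum_i 1-(1-c)^{1+k_i}$ (`expectedNullOverlap()`) ignores collapse and is
accurate only when same-block co-sampling is negligible; the test suite
compares the Monte Carlo null mean to the exact form at 3 standard
errors. What the generator does **not** emulate: LD decay with distance,
recombination hotspots, realistic MAF spectra, or correlation between
annotation density and gene proximity. Passing tests therefore validate
the machinery and its calibration under the stated model, not performance
on any real dataset.

## Numerical and degenerate-case choices

* Quartile edges use R's type-7 quantiles; degenerate inputs (all SNPs
  identical on an axis) collapse all mass into the lowest bin, which the
  matching contract handles unchanged.
* Variants on chromosomes absent from the TSS list get an effectively
  infinite distance and land in the top distance bin, keeping bin
  assignment total.
* An undersupplied bin (platform cannot furnish the demanded count)
  aborts with the bin label and deficit rather than silently relaxing the
  match.
* Unknown rsIDs queried against the LD table return empty partner sets;
  LD partners lacking a position in the variant catalog are an error by
  default and are dropped with a warning under the permissive flag (real
  LD tables contain variants absent from position catalogs).
* Empirical p-values live in $(0, 1]$: $r = 0$ is reported as the bound
  $< 1/n$.

## Validation scale and known limitations

The acceptance-level checks run at fixed, documented sizes: 200
enrichment-free studies of 500 null sets each for calibration; 50 studies
of 1,000 sets at 50% planting for power; 20 coverage/block-size
configurations for the analytic null mean; 1,000 randomized toy instances
for oracle equivalence; 10,000 iterations against exhaustive enumeration
for the shift test.

Two limitations are worth stating plainly. First, the empirical
exceedance p-value of an integer count statistic is **discrete and
sub-uniform**: its distribution touches the uniform only at the support
points $q_k = P(\text{count} \ge k)$. The rejection rate at any nominal
$\alpha$ is therefore conservative (never inflated) — the calibration
check confirms the rate at $\alpha = 0.05$ sits inside the exact binomial
band — but a Kolmogorov–Smirnov test against the continuous uniform can
reject when the null counts concentrate on few values, since the KS
distance approaches the largest point mass of the count distribution.
This is a property of the estimator, not a bias of the null construction
(the null mean matches its exact analytic expectation). Second, the
matched null controls TSS distance and LD partner count but no other
covariates (GC content, replication timing, chromatin context of the
platform itself); claims about real data inherit that limitation.
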