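---
title: "Mapping monogenic traits in RIL populations: bin markers, LOD scans and inconsistent rate analysis"
author: "iraQTL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping monogenic traits in RIL populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`iraQTL` implements the analysis chain used to map qualitative (binary,
monogenic) traits in a recombinant inbred line (RIL) population genotyped
by low-coverage sequencing: two fully homozygous, divergent parents are
crossed, the F1 is selfed for several generations (single seed descent),
and each line's genome becomes a mosaic of the two parental haplotypes.
Because each line is (nearly) homozygous, a site call can be polarized to
one of four states: P1 homozygote, P2 homozygote, heterozygote, or
missing. Every stage of the package works on that coding (0/1/2/NA).

The chain is: variant filtering → sliding-window bin-marker calling →
genetic map (Kosambi with RIL correction) → regression LOD scan with
permutation thresholds → inconsistent rate analysis (IRA) for
fine-mapping → codon-level annotation of candidate genes.

# The synthetic population

`simConfig()` / `simulateStudy()` generate the study the analysis
assumes, so every stage is testable without any external download.

* **Pedigree.** Each RIL is simulated as an explicit selfing pedigree
  from the F1: per meiosis the crossover count on a chromosome is
  Poisson with mean equal to its genetic length in Morgans, positions
  uniform in bp, no interference. `selfing_generations` (g) counts
  selfing rounds after the F1, so the population is the F(g+1)
  generation and residual heterozygosity decays as $(1/2)^g$; the
  default g = 6 reproduces an F7 population (≈ 1.6% heterozygous
  sites), matching the generation a survey would typically genotype.
* **Catalog.** Variant positions are uniform within chromosomes, with
  per-chromosome counts configurable; the defaults reproduce a
  nine-chromosome, ~401-Mb genome with 46,023 markers distributed very
  unevenly (two orders of magnitude in per-chromosome density), ~6.6%
  of them indels. Parents are homozygous-different at every catalog
  site, which is what makes a marker informative in this design.
* **Observation noise.** Calls are degraded in a fixed order: missing
  (default 0.30, matching sub-1× survey coverage), then a parent-flip
  error (0.01), then a spurious heterozygous call (0.02). True
  heterozygotes are only subject to missingness. The defaults are the
  package's model of low-coverage RAD genotyping; the generator does
  not model read depth, reference bias, or locus dropout explicitly.
* **Traits.** Each trait is monogenic with a configurable causal
  position and penetrance (default 0.97): per environment,
  independently, a line's phenotype equals its causal-genotype label
  with probability equal to the penetrance. Replicate environments
  therefore correlate strongly but not perfectly, reproducing the
  pattern seen in multi-environment scoring of stable qualitative
  traits. Residual heterozygotes at the causal locus are given the
  P2-parent phenotype (an arbitrary dominance convention, affecting
  ~$(1/2)^g$ of lines).

What passing simulation tests does **not** show: robustness to
segregation distortion, to structural variation between the parents, to
reference-bias-driven asymmetric missingness, or to mis-scored
phenotypes that correlate across environments.

# Variant and sample filtering

A site is kept when both parents are homozygous, non-missing and
different; then population-scale rules apply: minor allele frequency
≥ 0.1 (computed over homozygous calls only — at an advanced selfing
generation heterozygous calls are mostly noise), missing fraction ≤ 0.5
(denominator: all samples), heterozygous fraction ≤ 0.2 (denominator:
non-missing calls). All thresholds are inclusive for retention, so a
site exactly at a boundary is kept. Samples whose heterozygosity exceeds
30% of their non-missing calls are removed as likely contaminated or
mislabelled, since the expectation at F7 is ~1.6%.

# Bin markers and breakpoints

Genotypes are called in sliding windows of 15 consecutive retained
variants, advancing one variant at a time. A window is called for a
parent when more than 70% of its **non-missing** calls agree with that
parent, heterozygous otherwise. Missing calls are excluded from the
denominator because at 0.3 missingness a raw-count rule would force
spurious heterozygous calls; windows with fewer than 5 informative
calls defer to the nearest informative window. Runs of fewer than 3
identical window calls flanked by agreeing genotypes are smoothed away
(`min_run`).

Two consequences of the window rule deserve note:

* A clean homozygote→homozygote crossover necessarily produces a short
  pseudo-heterozygous transition zone: across the crossover no parent
  can exceed 70%, for about $w(1 - 2(1-c)) \approx 6$ windows. Such
  short heterozygous runs (shorter than one window size) between two
  *different* homozygous genotypes are collapsed into the breakpoint;
  longer heterozygous runs are genuine residual-heterozygosity
  segments and are kept.
* At a homozygote/heterozygote junction the window consensus flips
  early: it crosses the 70% cutoff once heterozygous content exceeds
  30% of the window, i.e. about $w(c - 0.5)$ variants before the true
  junction on the heterozygous side. Breakpoint flank bounds are
  therefore padded by $\lceil w(c-0.5)\rceil + 2$ variants on the
  heterozygous side, so that the true junction lies within the
  reported bounds. This padding is the analytic bias of the consensus
  rule, not a fitted constant.

The breakpoint point estimate is the midpoint between the last variant
whose window consensus supports the left genotype and the first
supporting the right; those positions are the flank bounds. Population
bins are the sorted union of all samples' breakpoint midpoints plus
chromosome ends; adjacent bins identical in every sample are merged, so
no sample recombines strictly inside a bin.

# Genetic map

Bins stay in physical order: the package deliberately does not re-order
markers (de novo grouping/ordering is a different problem, and bins
derived from physical coordinates are already collinear with the
genome). Between adjacent bins the observed recombinant fraction R is
computed over samples homozygous at both bins; RILs inflate R relative
to the single-meiosis fraction r, so R is corrected by
$r = R / (2(1-R))$ (the fixation limit of selfing RILs) before the
Kosambi function $\mathrm{cM} = 25\ln\frac{1+2r}{1-2r}$. The correction
can be disabled for raw-Kosambi comparisons. Intervals with no
informative samples get 0 cM with a warning — conservative, order
preserving.

Two accuracy notes, verified in the test suite: (i) near fixation
(g = 12, no noise, n = 200) a 100-cM chromosome is recovered within
15%; (ii) at F7 the recovered length is biased low by roughly a further
10% because junctions between homozygous and residual-heterozygous
segments are invisible to a hom–hom recombinant fraction. The map's
*order* and the downstream scan are unaffected.

# LOD scan

The scan is a Haley–Knott-style regression at every bin: with additive
coding (P1 = +1, HET = 0, P2 = −1) and cofactors C,
$\mathrm{LOD} = \frac{n}{2}\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$,
where the null model holds intercept + C and the alternative adds the
test marker. The additive effect is half the difference of the adjusted
genotype-class means (≈ 0.5 for a fully penetrant binary trait under
0/1 coding), and $R^2 = 1 - \mathrm{RSS}_1/\mathrm{RSS}_0$ per
position. Perfect fits are capped at LOD 50; positions with fewer than
10 informative samples return NA. A regression scan was chosen over an
EM mixture likelihood because with dense bin markers and a
near-Mendelian binary trait the two are practically indistinguishable,
and the regression is transparent and fast; the package does not aim to
match any particular interval-mapping program digit-for-digit.

Cofactors (composite-interval-mapping style background control) come
from forward selection (partial-F p < 0.01, at most 5), and are dropped
within 10 cM of the test bin. Permutation thresholds permute the
phenotype and rescan with simple marker regression (cofactors fixed at
none — the standard conservative choice for genome-wide thresholds);
the threshold is the (1−α) empirical quantile of the permuted maxima.
QTL are contiguous runs of bins with LOD > 3 and $R^2$ > 5%, split at
internal local minima that drop ≥ 1 LOD below both flanking maxima;
each peak is reported with the bins adjacent to it (flanking-marker
interval) and with the whole super-threshold region span. On a strongly
linked small chromosome the splitting rule can report several adjacent
peaks within one region — the same behaviour that splits a single
mapping region into named sub-QTL in practice.

# Inconsistent rate analysis

IRA is the fine-mapping statistic. Lines are split by phenotype into
group A (P1-parent phenotype) and group B; at an eligible locus (parents
homozygous-different, population missingness and heterozygosity each
≤ 50%) the inconsistent rate of group A is
$n_B / (n_A + n_B)$ counted within group-A lines, heterozygous and
missing calls excluded from both numerator and denominator, and
symmetrically for group B. At a locus tightly linked to the causal gene
the rate falls to the phenotype-error floor (≈ 1 − penetrance); at an
unlinked locus it rises to ≈ 0.5. Rates are averaged in 50-kb windows
stepped every 10 kb (anchored at coordinate 1, so region bounds land on
a 10-kb grid); windows with fewer than 3 informative loci are ignored.
Candidate regions are maximal unions of windows where **both** group
means are strictly below 0.10; regions separated by less than one
window width are merged, because a gap that cannot contain a single
fully-interior window cannot support two distinct candidates at this
resolution. Both grid-aligned and locus-tight bounds are reported.

Design notes: the strict cutoff means a window at exactly 0.10 is not
marked; heterozygous calls are excluded because the statistic is defined
over the two parental genotype classes; and IRA runs on the full
eligible marker set, not only on bin-map markers — using every variant
is what gives IRA its resolution advantage over the bin-level scan. With
a shallow, uniform recombination landscape the rate profile crosses the
cutoff gently, and sampling noise there can occasionally detach a small
satellite region from the main one; with the steep local landscapes
typical of gene-rich distal regions the crossing is sharp and the method
returns a single narrow interval. The acceptance-grade simulation
reports the frequency of the single-region outcome honestly rather than
hiding the boundary behaviour.

# Annotation

Gene models are read from GFF3 (one transcript per gene, CDS features in
transcription order); a variant's spliced-CDS offset is computed exon by
exon with reverse-complement handling on the minus strand and
$\mathrm{codon} = \lceil \mathrm{cds\_pos}/3 \rceil$. SNPs are
classified through the standard genetic code (synonymous /
nonsynonymous / stop gain / stop loss); indels are frameshift exactly
when the ref/alt length difference is not a multiple of 3. A gene in a
candidate region becomes a candidate when it carries at least one
parent-differentiating, protein-changing variant; region-restricted
noncoding variants are exported separately (they may be regulatory, but
no effect is claimed). Variants spanning a CDS boundary are classified
by their anchor base.

# Problem sizes used in the shipped checks

The test suite exercises: breakpoint recovery on 200 RILs × 2
chromosomes × 5,000 markers at 0.3 missingness and 1% error; scan
calibration on 200 null phenotypes with 300-permutation thresholds over
a ~250-bin map; IRA localization on 100 replicates of 400 RILs over two
3-Mb chromosomes (0.25 Morgan each, 1 marker / 5 kb); and the
conversion/annotation oracles at machine tolerance. These sizes were
chosen so the full chain, not a toy excerpt, runs in an ordinary
single-CPU session.

# Known limitations

* No crossover interference in the simulator (Poisson meioses); the
  Kosambi function downstream partially absorbs interference, so the
  simulated map and a Kosambi map are not perfectly matched models.
* Marker order is taken from the genome, never re-estimated; a
  mis-assembled reference would propagate into the map.
* The RIL correction assumes fixation; at F6/F7 residual heterozygous
  junctions shorten the recovered map slightly (quantified above).
* Indels are genotype labels in the population simulator; only the
  annotation fixtures carry real allele strings.
* The IRA cutoff is a fixed rule, not a significance test; its
  behaviour near threshold-grazing boundaries is discussed above.
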