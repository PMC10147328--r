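---
title: "Inferring expression inheritance and cis/trans regulatory divergence in hybrid introgression lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring expression inheritance and cis/trans regulatory divergence in hybrid introgression lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hilcis)
```

## The biological design

A hybrid introgression line (HIL) carries a chromosomal fragment of one
species — here an X-linked fragment of a *C. briggsae*-like donor, species B —
made homozygous (hemizygous in males) in the genetic background of a sister
species, a *C. nigoni*-like recipient, species N. Because every introgressed
allele now experiences the N-species *trans*-acting environment, comparing a
HIL's transcriptome with both parents partitions regulatory divergence
without allele-specific expression:

* if parents differ and the HIL matches B while differing from N, shared
  *trans* factors reconstitute the B expression state: **trans-only**
  divergence;
* if parents are indistinguishable yet the HIL differs from both, *cis* and
  *trans* changes must have diverged in opposite, compensating directions
  that cancel within each species but clash in the hybrid: **compensatory**
  divergence;
* if all three pairwise contrasts differ, both kinds of change are visible
  jointly: **combined** cis–trans divergence.

*Cis*-only divergence is invisible in this design (a HIL expresses only
N-background alleles for genes outside the introgression), which is why the
category set differs from F1 allele-specific studies. The same three-way
comparison also yields the classical inheritance-mode classification:
dominant (HIL matches one parent), additive (HIL intermediate), and
transgressive high/low (HIL outside the parental range). Transgressive
misexpression of genes *outside* the introgression is the signature of
Dobzhansky–Muller-type regulatory incompatibility this analysis quantifies.

## Pipeline overview

`run_hil_pipeline()` executes, in order:

1. **Ortholog restriction** (`restrict_to_orthologs()`): both
   reference-specific count matrices are reduced to the 1:1 ortholog set and
   re-keyed to a canonical ID. The canonical ID is the N-reference gene ID
   because the HIL genomic background is species N.
2. **Boundary detection** (`mapping_deltas()`, `segment_introgression()`):
   for each HIL, the per-gene statistic
   `delta = log2(mean count + 0.1 | refB) − log2(mean count + 0.1 | refN)`
   is computed over that HIL's samples only. Introgressed genes map well only
   to the B reference, so their deltas are strongly positive; parental
   samples are excluded because a B-species sample would flag the whole
   genome. The pseudocount 0.1 keeps all-zero genes at delta 0.
3. **Region-aware merge** (`merge_counts_by_region()`): genes inside a called
   segment take their counts from the B-reference matrix; all other genes
   from the N-reference matrix.
4. **Detectability filter** (`filter_detectable()`): genes with mean raw
   count ≥ 1 across all samples and at least one nonzero count are kept.
   No universal convention exists for "detectable"; this rule is simple,
   scale-free at typical depths, and configurable (`min_mean`).
5. **Three-way contrasts** (`build_triplet()`): negative-binomial Wald tests
   for B vs N, HIL vs N, and HIL vs B, with Benjamini–Hochberg correction
   within each contrast separately (the per-comparison convention of
   standard DE tools).
6. **Classification** (`classify_all()`): the two decision tables below.
7. **Comparative statistics** (`summary_report()` and friends): per-HIL DEG
   tallies, autosome/X Fisher tests, cross-HIL overlaps with Jaccard indices
   and hypergeometric p-values, category concordance matrices, and category
   tallies, restricted to the shared genome (genes outside every HIL's
   introgression).

## The differential-expression engine

The engine is a deliberately transparent NB pipeline; it is not a
re-implementation of any specific tool, and `classify_from_tables()` /
`triplet_from_tables()` accept externally produced, DESeq2-results-shaped
contrast tables whenever a different engine is preferred. Its components:

* **Size factors** — median-of-ratios: `s_j = median_g(k_gj / gm_g)` over
  genes with positive geometric mean `gm_g`, rescaled to geometric mean 1.
  This absorbs both sequencing depth and the genome-wide attenuation a
  divergent reference imposes on cross-species samples.
* **Dispersion** — per-gene method-of-moments on normalized counts,
  `alpha = max(0, (s² − m)/m²)` pooled across groups by within-group degrees
  of freedom, then shrunk 50/50 toward a mean–dispersion trend in the
  standard parametric form `alpha(mu) = a0 + a1/mu` (asymptotic dispersion
  plus shot noise), fitted by least squares to the positive raw estimates.
  Two details matter at triplicate scale. First, the shrink applies to
  *every* gene: with 2 degrees of freedom per group, roughly half of all
  truly overdispersed genes produce a raw estimate of exactly zero, and
  treating them as Poisson wildly understates their variance. Second, the
  blend is inflated by `(df+1)/df`; without it the Wald test's false-positive
  rate at the nominal 0.05 sits visibly above nominal in triplicate designs,
  and with it the rate is close to nominal (the factor fades out as
  replication grows). An earlier log-linear trend (log alpha on log mean)
  was rejected: when true dispersion is flat, the 1/mu shot-noise component
  drags the fitted line downward at high means, underestimating dispersion
  exactly where counts are largest and inflating false positives there.
* **Wald contrast** — plug-in group means of normalized counts;
  `log2fc = log2((muA + eps)/(muB + eps))` with a half-count guard
  `eps = 0.5 / median(s_j)`; the standard error follows from the NB variance
  of each group mean (`Var(k_j/s_j) = mu/s_j + alpha mu²`) by the delta
  method; two-sided p from the standard normal; genes with zero counts in
  both groups are definitional nulls (`log2fc = 0`, `p = 1`).
* **BH adjustment** — the classic step-up, written out in `bh_adjust()` and
  verified in the tests against both a brute-force implementation of the
  definition and `stats::p.adjust`.

Scope limits: one factor with two-level contrasts, no outlier (Cook's)
filtering, no independent filtering, no fold-change shrinkage — directions
come from the raw `log2fc` sign.

## The decision tables

With significance flags at `padj < 0.05` (one shared, configurable
threshold) and fold-change signs oriented HIL-minus-parent:

**Inheritance** (`classify_inheritance()`), evaluated in order: nothing
significant → *conserved*; HIL significantly above (below) both parents →
*transgressive high* (*low*), regardless of the parental contrast; all three
significant with HIL strictly between the parents → *additive*; parents
differ with HIL ≠ B only → *C. nigoni dominant*; parents differ with
HIL ≠ N only → *C. briggsae dominant*; everything else → *ambiguous*.

**Regulatory divergence** (`classify_regulatory()`): BvN and HvN significant
without HvB → *trans-only*; HvN and HvB significant without BvN →
*compensatory*; all three → *combined*; BvN and HvB without HvN →
*no effect*; none → *conserved*; else → *ambiguous*.

Two genuinely open choices were settled as follows:

* **Transgressive calls do not require the parents to differ** (default
  `require_parental_difference = FALSE`). This is the only reading under
  which a compensatory gene — whose parents are equal by definition — can be
  transgressive, and compensatory misexpression outside the parental range
  is precisely the expected phenotype. The stricter reading remains
  available behind the flag.
* **"Intermediate" for additive is a sign condition** (opposite
  HIL-minus-parent signs), not a magnitude window; a zero fold change next
  to a significant flag cannot be oriented and routes to *ambiguous*.

The tests enumerate all significance × direction patterns exhaustively and
verify totality plus the cross-table theorems (e.g. *C. briggsae* dominant
⟹ trans-only; additive ⟹ combined; transgressive with equal parents ⟹
compensatory).

## The synthetic-data generator

`sim_config()` / `simulate_hil_study()` emulate the study design the
analysis assumes: two parents plus two HILs with non-overlapping X-linked
introgressions (defaults ~4.8 Mb and ~7.4 Mb, mirroring the reported
fragments), three replicates per group, ~12,000 1:1 orthologs with ~17%
X-linked, NB counts with per-gene dispersion drawn log-uniform from
[0.01, 0.2], base means log-uniform from [20, 2000] expected counts, and
log-normal library-size factors (sd 0.1). Each gene gets one of five
architectures; with base mean `mu0`, effect size `d` (log2 units, default 2)
and random sign `s`, the expected-count triplets `(mu_B, mu_N, mu_H)` are:

| architecture | mu_B | mu_N | mu_H |
|---|---|---|---|
| conserved | mu0 | mu0 | mu0 |
| no_effect | mu0·2^(sd) | mu0 | mu0 |
| trans_only | mu0·2^(sd) | mu0 | mu0·2^(sd) |
| compensatory | mu0 | mu0 | mu0·2^(sd) |
| combined | mu0·2^(sd) | mu0 | mu0·2^(s'd') |

with the combined HIL mean intermediate, reinforced beyond B, or shifted
opposite to B in equal thirds by default. Default architecture fractions put
half the genome in *conserved* and spread the remainder roughly evenly
(12–13% each) across the divergent classes. Cross-reference mappability is a
single leak parameter `lambda` (default 0.05): reads from one species' DNA
are counted at rate 1 on their own reference and rate `lambda` on the other,
so a HIL's introgressed genes are attenuated on the N reference and its
background genes on the B reference. The default reflects mapping loss at
~21% synonymous-site divergence between these species.

What the generator does **not** emulate — and what passing tests therefore
cannot certify about real data: differences in tissue or cell-type
composition between hybrids and parents (a known confounder of whole-animal
RNA-seq, flagged as a caveat for this design), gene-length and GC bias,
correlated expression between genes, read-level mapping ambiguity (leak is a
deterministic rate, not a per-read process), partial or heterozygous
introgressions, and sequence evolution itself.

## Numerical and reporting conventions

* Coordinates are 1-based inclusive internally; BED input/output converts at
  the boundary. Segment bounds are the outermost flagged genes' annotation
  coordinates, matching how boundary genes are conventionally named.
* Segmentation defaults: delta threshold 1 (a two-fold mappability
  advantage), minimum 5 flagged genes per segment, at most 2 consecutive
  tolerated gap genes. The published analysis called boundaries by visual
  clustering of positive deltas; an explicit run rule is used here so the
  call is reproducible. At the default leak the delta contrast between
  introgressed and background genes is ~log2(1/lambda) ≈ 4.3, far above the
  threshold, so recovery is insensitive to these defaults within a wide
  range; they are not claimed to replicate the published boundary choice
  bp-for-bp.
* Overlap significance is the upper-tail hypergeometric probability
  (one-sided Fisher, enrichment direction); the autosome/X Fisher test is
  two-sided. Published analyses report "Fisher's exact test" without
  sidedness; enrichment questions are conventionally one-sided for overlap
  and two-sided for contingency comparison.
* Report rounding: percentages to the nearest integer and Jaccard indices
  to one decimal, both round-half-up (`round_half_up()`), matching the
  reporting precision of the figures this analysis reproduces.
* Dispersion floor 1e-8; size factors undefined (with a clear error) when no
  gene has positive counts in every sample.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: hand
arithmetic for size factors and mapping deltas, brute-force enumeration for
BH, hypergeometric and Fisher p-values, exhaustive pattern enumeration for
the decision tables, and generator-driven recovery runs for the integrated
pipeline. Calibration and recovery use deliberately modest problem sizes —
5,000 genes for the null false-positive-rate check (in [0.03, 0.07] at
nominal 0.05), 4,000 genes at effect size d = 3, dispersion 0.02 and five
replicates for category recovery (≥ 85% of trans-only and compensatory
truth recovered), and the full default study (12,000 genes, triplicates) for
introgression-segment recovery (Jaccard ≥ 0.95 against truth) — chosen so
the whole suite runs in well under a minute while keeping Monte-Carlo noise
far from the asserted margins. One test cross-checks the engine against
DESeq2 on a small strong-signal simulation (fold-change correlation and call
agreement), using it as an independent reference, never as the
implementation.

## Known limitations

* The engine's plug-in Wald test is approximate at very low counts; genes
  quantified through the poorly-mapping reference (cross-species samples at
  leak 0.05) carry most of the residual miscalling in recovery runs.
* BH is applied within each contrast, so the three flags of one gene are not
  jointly error-controlled; the *ambiguous* category absorbs most of the
  resulting incoherence, as in the published analysis.
* Boundary detection assumes bimodal mappability; at small divergence (leak
  near 1) deltas lose contrast and segments become uncallable — by design,
  since the dual-reference trick itself presupposes divergence.
* Concordance and overlap statistics treat genes as exchangeable; no
  correction for gene-gene correlation is attempted.
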