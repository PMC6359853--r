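---
title: "Detecting CpG traffic lights: model, matching and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting CpG traffic lights: model, matching and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgtl)
```

## The question and the statistical model

DNA methylation of a regulatory region often tracks the activity of the
gene it controls, but region-level averages (promoter, gene body) blur
the signal of individual cytosines.  A *CpG traffic light* is a single
CpG dinucleotide whose methylation profile across samples correlates
with the expression profile of an associated gene.  The unit of testing
is the CpG–gene *pair*: a CpG is paired with every gene for which it
lies within 10,000 bp upstream of the TSS through the 3′ gene end
(strand-aware, both boundaries inclusive), so one CpG can be tested
against several genes and vice versa.

For each pair the package computes the Spearman rank correlation between
the k pairwise-complete sample values of methylation (beta, in [0, 1])
and expression (RPKM).  Spearman is the right choice here: it is
invariant to the very different marginal shapes of the two measurements
(bounded, often bimodal betas; heavy-tailed RPKM) and to any monotone
normalization applied upstream.  Midranks are used in both vectors,
since both betas and RPKM produce ties.  Multiple testing is controlled
with Benjamini–Hochberg over the number of valid pairs; a pair is a
traffic light when q < 0.01 (strict inequality).  The untested universe
matters: pairs skipped for too few complete samples or zero variance
are excluded from the denominator and reported separately.

### P-values

For k ≥ 10 the two-sided p-value uses the standard t approximation
`t = rho * sqrt((k-2)/(1-rho^2))` with k−2 degrees of freedom; for
k ≤ 9 the exact permutation distribution is enumerated over all k!
orderings.  The crossover at 10 keeps the exact computation affordable
(9! = 362,880 orderings) while the working regime of the pipeline
(k = 20..48 after filtering) always sits comfortably in the
well-approximated range.  |rho| = 1 is mapped to p = 0 before
adjustment.

### Filters

In the strand-resolved count dialect, a (CpG, sample, replicate) value
is defined only when each strand carries at least 4 reads — the
threshold is inclusive — and its beta is the pooled methylated fraction
over both strands.  Replicates are averaged into one value per sample; a
sample keeps a value when at least one replicate passes, which is the
natural reading of "average replicates" when one replicate is simply
not covered.  CpGs with fewer than 20 defined samples are removed.
Missing values are handled by pairwise-complete deletion per pair;
expression is assumed complete.

## Region-average comparison and the permutation null

`region_average_analysis()` correlates the per-sample mean methylation
of the promoter (−1000..+500 around the TSS, endpoints inclusive and
configurable, since different boundary conventions are in circulation)
or the gene body (+500 to the 3′ end) with expression, correcting over
genes.  Genes whose region holds no covered CpG cannot be tested; the
counts are reported under both correction conventions (m = genes tested
and m = all genes) because the choice is genuinely ambiguous and the
difference is visible at small gene counts.

`permutation_null()` estimates the chance discovery count by decoupling
expression from methylation.  The default scheme applies **one** random
permutation of sample labels to the whole expression matrix per
iteration: this preserves gene–gene and CpG–CpG correlation structure
and breaks only the cross-coupling, which is the null of interest.  An
alternative per-gene shuffle (destroying gene–gene structure as well) is
available behind the `scheme` argument; it tends to give smaller null
counts and is not the default.

## Matched backgrounds

Enrichment statements about traffic lights are only meaningful against
controls with the same sequence context.  For each traffic light a
control CpG must satisfy, simultaneously:

* GC count in the 200 bp window centred on the CpG within 5% (value 80
  → interval 76..84, integer rounding at both ends);
* CpG dinucleotide count in the same window within 5% (a CG whose C
  lies on the last position inside the window still counts);
* matched distance to the TSS of the anchor gene: sites within 100 bp
  of the TSS are matched inside the same ±100 bp bin (distance 0 falls
  in the downstream bin), farther sites within 5% on log10(distance) on
  the same side (+1000 → 708..1413);
* when required, a correlation of the same sign with at least one
  associated gene.

Controls are drawn uniformly among eligible non-traffic-light CpGs,
without replacement within a replicate (a control used twice would
shrink the effective set size) and with replacement across the 50
replicates.  Matching is greedy in random traffic-light order; no global
assignment is attempted, matching the per-site description of the
procedure.  Unmatched traffic lights are flagged and reported, never
silently dropped, since silent dropping would bias enrichment toward
the matchable subset.  CpG-island membership is deliberately **not**
matched: island boundary calls are algorithm-dependent, so conditioning
on them would not reliably remove the composition bias they proxy.

For a traffic light associated with several genes, the distance
criterion is anchored at the gene of its most significant pair, and a
candidate's distance is measured to its own anchor gene — each site is
matched on its own regulatory geometry.

## Enrichment battery

* **Annotation tracks**: Fisher's exact test on the 2×2 table of
  traffic lights vs background, inside vs outside.  Background counts
  are computed per replicate; the rounded mean enters the table and the
  replicate SD is reported alongside (the mean ± SD convention used for
  plotting whiskers).  Sign-stratified rows (negative/positive ρ) are
  emitted next to the pooled row.
* **Score tracks** (conservation- and functionality-style per-base
  scores): "conserved" means strictly greater than the threshold;
  sites with no defined score are excluded and tallied.  Full score
  distributions can be compared with the two-sample KS test.
* **Chromatin states**: the TL/BG count ratio is computed per state and
  epigenome, cells with zero mean background count are left undefined,
  and the per-state summary is the arithmetic mean of defined cells
  over epigenomes, with absolute traffic-light counts carried along.
* **Gene sets**: observed vs expected = |set| × |TL genes| / |universe|,
  fold = observed/expected, Fisher p with Bonferroni over the number of
  sets tested in the run.
* **TFBS position profiles**: every CpG in a hit's window is projected
  to strand-normalized motif coordinates (offset 0 = motif 5′ end; a
  CpG occupies 2 bp, so on minus-strand hits the offset of its 5′ base
  after reversal is `len − 2 − o`).  Inclusion is decided in motif
  coordinates (offsets −shore .. len+shore−1), which for minus-strand
  hits differs by the 2 bp CpG footprint from the genomic half-open
  rule at the window edges.  Counts are normalized per 1000 hits so
  TFs with different hit counts are comparable.

## The synthetic-data generator

`simulate_config()` defaults describe the conditions the pipeline
targets: 48 samples, beta values with 20% per-cell missingness and at
least 20 defined values per retained site, log-normal (RPKM-like)
expression, and a small minority of planted CpG–gene couplings at
|ρ| = 0.9 with an even mix of signs.

Planted couplings are generated through a latent bivariate-normal rank
link: the gene's expression ranks are mapped to normal scores u, and the
CpG's betas are `pnorm(sign * r * u + sqrt(1 - r^2) * noise)` with
`r = 2 sin(pi rho / 6)` (Greiner's relation), so the realized Spearman
concentrates at the target without any Monte-Carlo calibration; at
target 1 the noise term vanishes and the realized coefficient is exactly
±1.  Because only ranks enter, the marginal shape of expression is
irrelevant — which is exactly the property of Spearman the pipeline
relies on.  Non-planted CpGs draw betas from a bimodal Beta mixture
(70% high, 30% low methylation), independent of all expression.
Missingness is applied per cell and sites falling below the defined-
sample minimum are dropped, never imputed, mirroring the removal rule
of the real pipeline.

Annotation tracks are built so that a planted site is covered with
probability exactly f·q (Bernoulli per site, with covering markers
added or 2 bp footprints punched out of random intervals as needed)
while ordinary CpGs see random intervals covering a fraction q of the
genome; tracks with f = 1 are plain random intervals built with no
reference to planted sites at all, which makes them exact nulls.  Score
tracks shift the planted sites' scores; segmentations relabel segments
holding planted sites with a configured probability; TFBS hits place a
configured fraction of planted sites at a recorded motif offset on a
random strand.  The manifest records every planted pair, factor, shift
and placement, which is what the recovery tests measure against.

What the generator does *not* emulate: realistic nucleotide
composition, CpG islands, bisulfite read-level noise, spatially
correlated methylation along the genome, or correlated expression
between neighbouring genes.  Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under the
stated model, not robustness to every artefact of real WGBS data.

## Numerical and boundary conventions

* User-facing positions are 0-based (position of the CpG's C; the site
  occupies [pos, pos+2)); intervals are half-open.  Conversion to the
  1-based closed convention of GenomicRanges happens at one internal
  boundary.
* The pairing window boundary is inclusive at exactly −10,000 and at
  the 3′-end base; promoter endpoints are inclusive and configurable.
* Tolerance intervals round to the nearest integer at both ends;
  q-values exactly equal to the FDR threshold are *not* called
  (strict inequality).
* Fixed seeds make every stage — generator, matching, permutations —
  byte-identical across runs; each pipeline run writes its resolved
  configuration and a structured log.

## Problem sizes used in the test suite

The packaged checks run at desk scale, chosen once: parameter-recovery
panels of ~20,000 pairs with 200 planted couplings over 20 seeds
(sensitivity ≥ 0.9, 100% sign agreement among detections, realized FDR
≤ 0.03 at nominal 0.01); a promoter design of 40 genes × 10 promoter
CpGs with one causal CpG each, where single-CpG calling finds more genes
than promoter averaging in at least 19/20 seeds and the permutation
null stays below 5% of the observed count; 50 background replicates
re-validated by an independent checker with zero violations; and 200
null-track Fisher tests whose rejection rate at 0.05 stays within three
standard errors of nominal.  Headline genome-wide counts from full-size
compendium reprocessing are outside what these synthetic panels can or
should reproduce.

## Known limitations

* The t approximation for Spearman p-values is an approximation; at
  k = 20 its tail behaviour is adequate for FDR control (verified by
  the null-calibration tests) but exactness is only guaranteed in the
  enumerated small-k regime.
* Greedy per-site matching can leave traffic lights unmatched even when
  a global assignment exists; unmatched fractions are reported.
* The Fisher aggregation over background replicates uses the rounded
  mean count, a convention choice; the replicate SD is reported so the
  sampling spread is never hidden.
* Genome builds are treated as opaque labels; no coordinate conversion
  between assemblies is attempted.
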