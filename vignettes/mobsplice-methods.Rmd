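---
title: "Methods: screening insertion polymorphisms for splicing effects"
author: "mobsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening insertion polymorphisms for splicing effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobsplice)
```

## Overview

`mobsplice` models a three-stage screen for splicing QTLs caused by
polymorphic mobile-element insertions (typified by Alu elements):

1. **Where do insertions sit relative to exons?** Intronic insertion
   variants are profiled by their nearest-exon distance, and the
   depletion of insertions in the ~100 bp zone flanking exons is
   quantified.
2. **Which variants could plausibly alter splicing?** Variants within a
   window of an alternatively used exon are prioritized and annotated.
3. **Do they?** Splicing readouts (reporter gels, fragment-analyzer
   peaks, isoform-specific qPCR) are converted to percent exon skipping
   and tested against insertion genotype or construct identity.

This vignette records the modelling assumptions, parameter choices,
numerical conventions and the design decisions taken where more than one
reasonable convention exists.

## Coordinates and the distance convention

All intervals are 0-based half-open internally (the BED convention);
GFF3's 1-based inclusive coordinates are converted on read. An insertion
variant is a single base position: the base immediately 3′ of the
integration junction on the plus strand. Insertion catalogs mapped to
single-base resolution give exactly this; the inserted element itself is
absent from the reference, so no footprint interval exists to measure
from.

Distance to an exon is 0 inside the exon and otherwise one plus the
number of bases strictly between the insertion base and the nearest exon
edge — so the base adjacent to an exon edge is at distance 1. This
matches the behaviour of `bedtools closest -d`, the de facto standard for
nearest-feature distances, and makes "within 100 bp" an inclusive
`distance <= 100` test. When a variant is exactly equidistant from two
exons, the transcriptionally downstream exon is reported and the row is
flagged `tie = TRUE`: deterministic and auditable rather than silently
arbitrary. Variants inside overlapping genes yield one row per containing
gene, because position and orientation are gene-relative; variants in no
gene body are emitted with an `intergenic` flag rather than dropped.

## Exon classification

An exon is *alternatively used* when it is skipped in at least one
isoform or used with alternative 5′/3′ boundaries. Precisely: an exon is

- **constitutive** when present with identical boundaries in every
  isoform of its gene;
- **skipped** when at least one isoform spans the exon's locus without
  any exon overlapping it (an isoform that simply ends before the locus
  — an alternative terminal structure — does not count as skipping it);
- **alt5/alt3** when another isoform uses an overlapping exon with a
  different transcription-5′ or 3′ boundary, combinations reported as
  `alt5+alt3` or `skipped+alt-ends`.

Non-coding isoforms are treated identically to coding ones; isoform
biotype carries no weight in the classification. The only ambiguous
corner is an exon absent solely from non-spanning isoforms: it is
reported constitutive (it is constitutive everywhere it can be observed),
a choice made once and applied uniformly.

## Depletion profiling

Distances are binned left-open/right-closed in 25 bp bins — `(0,25]`,
`(25,50]`, … — so that a distance of exactly 25 bp counts as "within
25 bp"; distances beyond a configurable maximum (default 2500 bp) pool
into an overflow bin. Proportions are normalized by the number of
intronic elements.

Depletion near exons is summarized as a **retention ratio**: the per-bp
density of insertions with nearest-exon distance ≤ 100 bp divided by the
per-bp density farther away. The exposure denominators (intronic bp
inside/outside the window) are computed from the annotation itself rather
than assumed uniform, because short introns put a large share of their
length inside the window and a naive count ratio would overstate
depletion. The CI is a percentile bootstrap over elements (default 1000
replicates); a seed is required — no function in the package consumes
hidden RNG state.

## Candidate statistics

Counts of candidate features (sense vs antisense orientation, upstream vs
downstream position) are tested against a 50/50 expectation with a
Pearson chi-square, df = 1, **without** Yates continuity correction: for
counts in the dozens the uncorrected test is standard, and it is the
variant consistent with the orientation test's conventional reporting
(42 vs 31 gives p = 0.1979). The one-sample proportion test against an
externally supplied expected fraction uses the same 2-cell Pearson form;
the expected fraction is a caller input because it derives from a
genome-wide exon-class mix that depends on the annotation release in use.

Pairwise LD is computed from a 2×2 haplotype count table:
D = p_AB − p_A·p_B, D′ = |D|/D_max with the standard D_max, and
r² = D²/(p_A p_a p_B p_b), with a multinomial bootstrap percentile CI for
D′. Monomorphic loci are an error, not an NA.

Frameshift annotation is the length rule: an exon whose length is not a
multiple of three shifts the reading frame of every downstream codon when
its inclusion changes.

## Reporter quantification model

The signal model for gels and fragment-analyzer traces is that a band's
intensity is proportional to fragment length × molar abundance (each
molecule contributes staining in proportion to its length). Molar
isoform fractions are therefore recovered as
`(intensity/length) / Σ(intensity/length)`, and percent skipping is 100 ×
the summed molar fractions of isoforms lacking the target exon — which
generalizes unchanged to loci with three or more bands. Peak height vs
peak area are just different intensity columns under the same formula.
Percentages are displayed at two decimals; full precision is retained
internally. Background subtraction is left to the caller: intensities are
taken as provided.

qPCR relative expression averages replicate Ct values at the Ct level
(variance-stable for the small triplicate counts typical of these
assays), then ΔCt = Ct_target − Ct_reference and 2^−ΔCt. The isoform
ratio of two assays sharing a reference reduces algebraically to
2^(Ct_include − Ct_skip); the implementation computes it through the two
relative expressions and the identity is covered by tests. Undetermined
Ct values are rejected, with table readers dropping and naming such rows.

## Statistical layer

Construct comparisons use the unpaired Student t-test by default (Welch
as an option): group sizes in reporter experiments are tiny and equal
(typically 4 vs 4 pooled over clones and replicates), where the
equal-variance test is conventional, and it preserves the F = t² identity
with the one-way ANOVA used for genotype effects. Degenerate inputs are
reported, not crashed: two identical constant groups give p = 1 with a
`degenerate` flag, and an all-constant ANOVA panel gives F = 0, p = 1.

Family-wise correction is Bonferroni: threshold α/m displayed at two
significant figures (0.05 over 21 tests → 0.0024; over 26 → 0.0019), full
precision retained for the comparison itself. The family size *m* is a
*declared* input, never silently inferred from the comparisons actually
run: pre-registered testing plans sometimes exclude comparisons (a
declared family of 26 for eight groups, where all pairs would be 28), and
the report errors if the declared family is smaller than the tests
performed. The per-factor one-way ANOVA (genotype; clone) is the minimal
model for screening which factors matter; no factorial model is fitted.

## The synthetic-data generator

The generator's defaults are the study conditions the analysis assumes:

- **Annotation**: 20 genes, 4–10 exons of 50–300 bp (under a uniform
  length draw about two thirds of exon lengths are not divisible by 3),
  introns of 500–3000 bp; 30% of internal exons get a skipping isoform.
- **Insertions**: candidate positions uniform over intronic bp; positions
  within 100 bp of an exon are retained with probability *r* (default
  0.3, i.e. 70% depletion — the qualitative regime of the genome-wide
  near-exon deficit). Subfamily labels default to a skew in which the
  young, commonly polymorphic subfamilies (AluYa5/Yb8/Yb9) together make
  up 57.5%; element lengths 260–320 bp emulate mostly full-length
  elements including their polyA tails.
- **Gels**: intensity = length × molar × exp(ε), ε ~ N(0, σ²) with
  σ = 0.1 — multiplicative noise keeps intensities positive and matches
  the roughly constant CV of densitometry.
- **Genotype panels**: dose ~ Binomial(2, MAF) under Hardy–Weinberg with
  MAF = 0.285 (a realistic common-insertion frequency; the canonical
  deep-dive locus in this literature has exactly this MAF, where 12
  sampled individuals split ~7/4/1 across genotypes). Skipping follows
  logit(ψ) = β0 + β1·dose + N(0, σ²) with β0 = −1.22 (≈23% baseline
  skipping, matching a ~77% inclusion pre-insertion allele), β1 = 1 logit
  per allele and σ = 0.3; the logit link keeps ψ in (0,1) by
  construction.
- **qPCR**: Ct_skip − Ct_include = −log2(ratio) plus N(0, 0.2²) cycles
  per replicate, triplicates per primer pair.

Every simulator returns its ground truth alongside the data, and all
randomness flows from an explicit seed: identical configurations are
byte-identical.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequence-level splicing mechanism (splice-site
strength, regulator binding, RNA secondary structure), overlapping genes,
nested or intron-retaining isoforms, tissue-specific isoform usage,
linkage between variants, amplification-efficiency differences between
qPCR assays, and gel background or saturation. Parameter-recovery results
demonstrate that the estimators are consistent under the stated model,
not that the model captures every property of laboratory measurements.

## Problem sizes and numerical choices

Simulation-based checks use sizes chosen to give comfortable statistical
resolution at interactive runtimes: retention recovery uses catalogs of
5000 insertions over 20 genes averaged across 20 draws (mean within 5%
relative error of the simulated value); gel-recovery checks use 1000
replicates (unbiased within 0.5 percentage points at σ = 0.1); null
calibration uses 2000–4000 simulations (KS uniformity at α = 0.01) and
power checks 200 simulations at the study-scale group sizes (4 vs 4
constructs; Hardy–Weinberg panels of 50).

Numerical conventions worth stating: GC matching for spacer design is an
exact count, round-half-up (`round(length × target)` G/C bases placed
uniformly), not per-base Bernoulli — the invariant is exactly testable
and the realized GC never drifts from the target. Scrambles are uniform
unconstrained permutations of the whole element including the polyA tail;
no motif avoidance is attempted (screening scrambles for accidentally
created splice motifs is left to the caller, and evaluating two
independent scrambles per locus — enforced by distinct recorded seeds —
is the practical guard). Bootstrap CIs are percentile-type. Ties,
degenerate tests and 0/0 bin ratios are flagged in outputs rather than
silently resolved.

## Interfaces

The package's surface is its functions, composed by two orchestrators:
`run_screen()` (simulate or read inputs → distances → profile → depletion
→ candidates, with a JSON manifest of file hashes, counts and the seed)
and `run_sqtl()` (measures + genotypes → ANOVA + dose tests → TSV/JSON
report). Readers and writers cover GFF3/BED12 annotation, extended-BED
variant catalogs, band and Ct TSVs, FASTA construct series and TSV
profiles; `scripts/acceptance.R` is the reproducibility entry point.

## Known limitations

- The exon classifier reasons over isoform exon structures only; it does
  not consult expression support, so rare annotated isoforms count as
  much as dominant ones.
- Exposure computation enumerates intronic positions; for genome-scale
  annotations a closed-form interval computation would be preferable.
- LD confidence intervals are bootstrap-based; likelihood-profile
  intervals are not implemented.
- The reporter model assumes complete, unbiased RT-PCR amplification of
  all isoforms; strong length bias in amplification would propagate into
  percent-skipping estimates.
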