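---
title: "Methods: circRNA BSJ consolidation, conservation and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circRNA BSJ consolidation, conservation and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circRPL)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates and detector harmonization

All modules share one coordinate convention: **1-based, fully closed**, the
native convention of CIRI2-style output. The DCC dialect (0-based start,
1-based end) is converted on read; each reader declares its dialect
explicitly rather than guessing. Two BSJs are the same circRNA exactly when
`(chrom, start, end, strand)` are equal.

Consolidation is the **exact intersection** of the two detectors' BSJ sets —
no positional fuzz. Detectors do wobble by ±1 nt at splice sites, and the
generator can plant such jitter (`coord_jitter`); an exactly-intersecting
pipeline then loses those calls, which is the behaviour under test, not a
defect. The ±2 nt tolerance window exists in two other places (exon-boundary
matching during classification, conservation matching) where it reflects
annotation wobble rather than detector disagreement. Strand agreement is
required by default (`match_strand = TRUE`); whether the original
intersection required it is unknowable from the outputs, so it is a flag,
and with it off the consolidated strand is resolved per BSJ by majority vote
with defined strands preferred over ".". Junction-read counts always come
from the single designated quantification table, never from detector
internals and never summed across detectors; a consolidated BSJ missing
from that table gets explicit zeros and a warning. Duplicate calls within
one detector collapse to the maximum count, defensively, with a warning.

## Classification and nomenclature

A BSJ is *exonic* when its start lies within ±2 nt of an exon start (the
back-splice acceptor) and its end within ±2 nt of an exon end (the donor) of
one gene; *intronic* when the whole span sits strictly inside a single
intron; *intergenic* when it overlaps no gene body. Spans that overlap a
gene but fit neither pattern default to exonic with the best-overlapping
gene — a deliberate catch-all so every record is classified. Host-gene ties
break by largest overlap fraction, then alphabetically; both rules exist
only to make the output deterministic.

Names follow the field's convention: `hsa-circGENE-NNN` (exonic),
`hsa-ciGENE` (intronic; `-NNN` only when a gene hosts several), and
`hsa-circChromK-NNN` (intergenic). The sequential three-digit counter is
ordered by genomic position `(start, end)` within the naming group. Ordering
by position (rather than discovery order) makes naming a pure function of
the record set — permuting the input can never change a name — at the cost
of not reproducing any particular historical numbering, which would require
the original call set anyway.

## Conservation classification

The 5′ and 3′ splice positions are defined on the transcribed strand: for
"+" records the 5′ acceptor is `start` and the 3′ donor is `end`, flipped
for "−"; unstranded records use `(start, end)` as `(5′, 3′)`. Each position
is lifted through an interval map (a liftOver-style object: equal-width
source/target intervals with constant offset and optional orientation flip;
real chain files are out of scope). If either site fails to lift the BSJ is
**not-aligned**. Otherwise a catalogue circRNA "uses" a site when either of
its termini falls within ±`window` nt (default 2) of the lifted position —
termini rather than strand-resolved sites, because the lift map may flip
orientation, and matching on strand as well would double-count that flip.
The six categories follow from which sites are used and whether one
catalogue entry uses both: **homologous** (one entry uses both sites),
**both sites utilized** (both used, only by different entries), **5′/3′ site
utilized**, **no homologous**. The categories are mutually exclusive and
exhaustive by construction, and enlarging the window can only move a BSJ
toward homologous, never away — both properties are asserted in the tests
against an exhaustive brute-force classifier.

## Expression filter, normalization and PCA

A circRNA is expressed in a project when it has at least `min_count` (5)
junction reads in at least `ceiling(min_fraction * n)` samples; "half of the
samples" with 9 samples therefore means 5. Size factors are the **total
library sizes**, so normalized counts are counts per sequenced read and
baseMeans land at 1e-6–1e-7 for junction reads — the intended scale, since
junction-spanning reads are a tiny fraction of a total RNA-seq library. A
DESeq-style median-of-ratios mode exists for comparison but is not the
default. PCA operates on `log2(normalized + pseudocount)` with a pseudocount
of 1e-7 (about one read in a 10-million-read library — small enough not to
mask expressed circRNAs, large enough to keep zeros finite); scores are
centered, components ordered by variance explained, and each component's
sign fixed so its largest-magnitude loading is positive, making outputs
reproducible across BLAS implementations.

## The NB Wald test

Per circRNA, counts follow `K_ij ~ NB(mu_ij, alpha_i)` with
`mu_ij = s_j * q_i * 2^(beta_i * x_j)`. With a two-group design the group
log-means decouple, so each is a one-dimensional Newton MLE with
library-size offsets. The dispersion comes from the Pearson moment equation
`sum (k - mu)^2 / (mu (1 + alpha mu)) = n - 2` — a method-of-moments
estimator whose degrees-of-freedom correction accounts for the two fitted
means — floored at 1e-8. The standard error uses the expected Fisher
information at the MLE.

The Wald statistic is referred to a **t distribution with n − 2 degrees of
freedom** rather than the standard normal. At the sample sizes this design
typically has (5–10 per group), the dispersion estimate is noisy and a
normal reference is visibly anticonservative (raw rejection near 9% at a 5%
level in the package's own null simulations); the t reference restores
calibration (≈5%, Kolmogorov–Smirnov distance from uniform ≈0.02), which is
what the acceptance suite checks. This, the moment dispersion, and the
absence of shrinkage, Cook's filtering and independent filtering are the
documented differences from DESeq2-style analysis: the test is judged by
calibration and recovery on planted truth, not by equality with any
particular implementation.

Degenerate rows are kept, not dropped: all-zero rows report `p = 1` and
log2FC 0; a group with all-zero counts gets a 0.5 pseudo-count on its group
total so the fold-change stays finite, and the row is flagged. BH adjustment
runs over all tested circRNAs in the project; significance uses strict
inequalities (`padj < 0.05`, `|log2FC| > 0.58`). Each project (tissue) is
tested separately — tissues differ too much for a pooled dispersion to be
meaningful — while PCA alone pools projects to show between-project
variation.

## Over-representation analysis

The query is the set of host genes of expressed circRNAs; the background is
the expressed-gene universe supplied as a file (in synthetic runs the
generator emits it; retrieving a live annotation database is out of scope,
keeping results database-version independent). The test is the upper
hypergeometric tail `P[X >= k]` with all four counts restricted to the
background; sets with fewer than 5 or more than 400 background members are
excluded before testing; BH correction replaces source-specific multiple
testing schemes. Significant terms are clustered by Jaccard similarity
(edge at ≥ 0.5, the EnrichmentMap default family) and components with fewer
than three sets are dropped — a flat-table stand-in for a network
visualization.

## What the generator emulates — and what it does not

`simulate_world()` plants, per circRNA: locus class and host gene, catalogue
membership, DE status and signed log2 fold-change, conservation category,
and per-detector detectability. Counts are NB with a single shared
dispersion (`Var = mu + alpha mu^2`, default `alpha = 0.2`, a typical
bulk-RNA-seq biological CV), means proportional to library size (uniform in
5–20 million reads, a realistic span for the public datasets this design
mirrors), and a log-normal spread (sd 1) of baseline expression around
`mean_expression = 30` junction reads. Defaults describe a small two-project
study with 5 + 5 samples per project, 70/15/15% exonic/intronic/intergenic,
60% known, 45% homologous, 10% unliftable, 5% one-detector dropout, 2%
coordinate jitter, 20% DE at |log2FC| = 1.

Two simplifications matter when reading test results. First, every circRNA
owns globally unique splice positions, so each site can be given a private
lift target and catalogue neighbourhood — this is what makes the planted
conservation category recoverable for 100% of circRNAs; real circRNAs share
splice sites within genes. Second, there is no batch structure beyond
library size, no read-level error, and detector errors are independent
single-site events. Passing tests therefore demonstrate the correctness of
the algorithms under the stated statistical model, not robustness to
correlated detector artefacts or shared-site ambiguity in real data. The
enriched gene set is a positive control built from hosts of well-expressed
circRNAs (80% of members by construction) against uniformly drawn decoy
sets.

Problem sizes in the tests and acceptance script were chosen to make the
statistical checks tight while staying comfortably interactive: 2000
circRNAs with 5 vs 5 samples for null calibration, 2000 with 10 vs 10 (a
quarter DE at |log2FC| = 2) for recovery, 1000 for the conservation stress
check, and 30 seeded replicates for the enrichment ranking property.

## Numerical and degenerate-input choices

* Newton iterations for the group log-mean stop at a step below 1e-10; the
  starting value is the moment estimate, which is already the MLE when the
  dispersion term vanishes.
* The Pearson dispersion root is bracketed from 0 upward and solved with
  `uniroot` at tolerance 1e-10; when the equation has no positive root the
  floor (1e-8) is used, giving an effectively Poisson fit.
* Writers emit LF-terminated, unquoted TSV deterministically, so identical
  inputs always give byte-identical outputs — the end-to-end determinism
  contract is hashed file trees, with no timestamps in any table.
* Empty inputs flow through every stage (empty call files, empty
  intersection, all-filtered matrices, empty query) and produce empty,
  schema-stable outputs rather than errors; genuinely invalid inputs
  (negative counts, end < start, overlapping lift-map sources, conditions
  with fewer than two samples) raise classed errors naming the file or
  field.

## Known limitations

* Exact-match consolidation discards near-miss detector pairs; a fuzzy
  intersection mode is deliberately out of scope.
* The DE model is two-group only — no covariates, batch terms or multi-level
  designs — and per-feature dispersion without shrinkage loses power at very
  small n relative to moderated methods.
* Conservation handles one target-species catalogue per run and interval
  maps only; real chain files (split/partial alignments) are not parsed.
* Internal circRNA structure (exon composition, isoforms) is not inferred;
  a BSJ alone cannot recover it.
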