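---
title: "Methods: measuring NLR copy number variation across genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring NLR copy number variation across genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrcnv)
```

## The problem and the model

Plant NLR (nucleotide-binding leucine-rich repeat) gene families evolve
by a birth-and-death process: local duplication — predominantly tandem
(a copy immediately adjacent to its source) and proximal (a copy within a
few gene positions) — expands clusters of NLR loci, and some copies
subsequently decay into pseudogenes. Comparing several de novo assemblies
of one species can therefore reveal discrete classes of genotypes with
high and low NLR copy number, driven almost entirely by local duplication
on a few NLR-dense chromosomes.

`nlrcnv` operationalises that comparison as five stages, each consuming
plain evidence tables (GFF3 gene models, Interproscan-style domain hits,
motif caller output, BLAST-like similarity and tBLASTn-like pseudoexon
hits) rather than raw sequence, so the stages can be run, inspected and
tested independently.

## Stage parameters and their defaults

All thresholds live in three parameter objects so a run is fully
described by its configuration.

**NLR identification (`classify_thresholds()`).**
Seed-quality Pfam hits (NB-ARC at e ≤ 1e-60, TIR and RPW8 at e ≤ 1e-40,
both inclusive) select the domain sequences from which lineage-specific
HMMs are built externally; the package extracts the domain subsequences
and collapses near-duplicates with greedy centroid clustering at
`rep_identity = 0.98`. A protein is called an NLR when a domain HMM hit
reaches e ≤ 1e-4 or the NLR-motif caller reports a CC motif. Architecture
follows a fixed rule order — TIR → TNL, RPW8 → RNL, Rx-type CC (PF18052)
or parser-CC together with a COILS coiled-coil → CNL, otherwise NL. The
order matters only for rare conflicted proteins (both TIR and RPW8);
those are classified TNL and reported, since the rules are stated in that
sequence and a dual-domain fusion is biologically closest to a TNL.
NB-ARC-only proteins fall through to NL with `complete = FALSE` and
`has_lrr = FALSE`, so they remain separable for assembly-quality checks.

Identity for clustering is global-alignment identity: matches divided by
all alignment columns, gaps included, with alignment chosen under
match +1 / mismatch 0 / gap −1. Centroid-based tools define identity
slightly differently, but at a 98% threshold on near-duplicate domain
sequences the definitions agree; the unit tests pin this package's
definition exactly. Processing order is decreasing length, then name, so
the output is deterministic and permutation-invariant whenever lengths
are distinct.

**Collinearity and duplication (`collinear_params()`).**
Chaining uses `match_score = 50`, `gap_penalty = -1`, `match_size = 5`,
`max_gaps = 20` and an e-value cutoff of 1e-10, the standard
MCScanX-style setting. Chain score is
`match_score · anchors + gap_penalty · Σ skipped ranks`, where the
skipped ranks between consecutive anchors are `(Δr_a − 1) + (|Δr_b| − 1)`.
Chains are extracted greedily in descending score order and an anchor pair
is never reused; within-chromosome chains are allowed but discarded when
their two rank intervals overlap (those are the trivial near-diagonal
self-matches, not duplicated segments). Duplication classes are assigned
with precedence `wgd_segmental > tandem > proximal > dispersed >
singleton`, matching the progressive-refinement direction in which the
classes are defined. Rank distance — not intervening-gene count — defines
"away": distance 1 is tandem (immediately adjacent), 2–20 proximal; the
bound is exposed as `max_proximal`. Repeat-control parameters of the
original classifier (repCut/repDiv) are not reimplemented; the precedence
rule handles large tandem families.

**Cluster detection.** Windows of 1 Mbp tile each chromosome from
coordinate 1. A gene is counted in the window holding the majority of its
span; an exact 50/50 split goes to the left window so every NLR is counted
exactly once (a strictly-more-than-half rule would leave such genes
uncounted). Adjacent occupied windows are merged to a fixpoint — provably
the maximal runs of consecutive occupied indices, which is what the
implementation computes directly; the tests verify the fixpoint against
literal pairwise merging under random merge orders. Runs with ≥ 3 NLRs
are clusters. Unplaced scaffolds (`Chr0`) are excluded from clustering,
because window adjacency is meaningless across unordered scaffolds, but
Chr0 genes still appear in per-chromosome counts.

**Pseudogenes (`pseudo_filter()`).** Candidate hits (e ≤ 1e-20) must be
strictly non-genic (no 1-bp overlap with an annotated gene span), longer
than 30 aa, above 40% identity, and without a repeat-library match at
e < 1e-5; every removal is counted by reason. Surviving pseudoexons are
sorted by position and consecutive hits are linked when they share the
same best-hit parent (lowest e-value, ties by identity then id) and their
gap is at most the 99th percentile of the genotype's intron-length
distribution — "inside the percentile" is read inclusively; for a
continuous gap distribution the choice is immaterial but it must be
fixed. The intron distribution pools all annotated genes, not only NLRs,
and the quantile uses linear interpolation between order statistics.
Frame concordance across linked pseudoexons is recorded but not enforced,
since linking is defined by parent identity and gap alone.
Single-pseudoexon contigs count as pseudogenes by default (`min_exons`
exposes the choice): a single-exon parent legitimately yields a
single-exon pseudogene. Contigs whose six-frame translations contain none
of the common NLR domains (LRR PF00560/PF07725/PF12799/PF13855, NB-ARC
PF00931, TIR PF01582/PF13676, RPW8 PF05659, CC PF18052) are removed,
which protects against integrated non-NLR domains seeding false
pseudogenes.

**Statistics.** The High/Low CNV split is computed (1-D 2-means over the
n−1 sorted cut points, with a gap statistic quantifying discreteness),
never hard-coded at an observed gap, so the same code applies to
synthetic data. Group uncertainty uses SEM and t-based 95% intervals; the
interval construction behind published figures is typically not
specified, and the t interval is the conventional choice at these group
sizes. The Mann-Whitney test enumerates all labelings exactly up to a
combined n of 12 (covering 7-vs-4 comparisons) and is two-sided via the
distance of U from its null mean, which handles ties and reduces to the
classical two-sided doubling for tie-free data; larger samples use the
tie-corrected normal approximation without continuity correction. The
complete-vs-partial table uses Pearson's χ² without Yates correction,
matching a plain "Pearson's χ² test". Negative-binomial count models are
deliberately delegated to `MASS::glm.nb`: the pipeline's contribution is
the counts, not the fit.

## The synthetic generator

`sim_config()` describes the study conditions the generator emulates:
several genotypes of one species, 10 ordered chromosomes plus an unplaced
`Chr0`, NLR founders concentrated (weight 0.75) on four designated
chromosomes, and two duplication regimes. High-regime genotypes run 5
events per founder with event probabilities 0.5/0.3/0.1/0.1
(tandem/proximal/dispersed/segmental); low-regime genotypes run 1 event
with 0.05/0.05/0.8/0.1. Those settings put 80% vs 10% of duplication
mass on local events and reproduce the qualitative observation the
pipeline is built to measure — a roughly 3-fold, clearly bimodal gap in
total NLR count with cluster expansion on the NLR-dense chromosomes.
Sequence identity decays linearly at 1.5% per duplication event — enough
to exercise the 98% clustering threshold and the 40% pseudoexon identity
filter without a substitution model. A duplicate decays into a pseudogene
with probability 0.1, emitting 1–4 pseudoexon fragments whose gaps are
drawn below (or, for planted violations, above) the genotype's intron
q99. Intron lengths are log-normal around 300 bp; at desk scale
chromosomes are 5 Mbp with ~300 background genes and 25 founders per
genotype. Each planted pseudogene is centred in its own wide intergenic
gap so planted fragment chains cannot merge across pseudogenes.

Two deliberate simplifications: chromosomal nucleotide sequence is never
generated (the pipeline consumes tables, so pseudoexon evidence is
emitted directly as tables with planted coordinates), and protein
sequences exist only for NLRs (domain extraction and clustering need
them; background decoys need only their near-threshold e-values).
Consequently, passing recovery tests demonstrates the correctness of the
selection, classification, chaining, windowing and linking logic under
planted truth — they do not validate upstream domain scanners, aligners
or assembly quality on real data, which enter the pipeline as external
evidence.

Determinism: every randomised emission derives from the master seed
(per-genotype streams are drawn once from it), and a fixed seed
reproduces byte-identical outputs.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere in memory (the GFF3
  convention); BED export converts to 0-based half-open at the boundary.
* Multi-isoform genes are represented by the mRNA with the largest summed
  exon length (ties by id); which transcript published counts used is
  typically unstated, and one protein per gene matches per-gene counting.
* Empty inputs return typed empty tables; an annotation without introns
  makes the intron quantile an error instructing a configured fallback
  rather than silently linking nothing.
* DP chaining ties prefer the earlier predecessor; blocks are reported in
  descending score order with deterministic ids.
* `assign_cnv_groups` with all-equal totals returns a single group with a
  warning rather than an arbitrary split.
* Genes longer than one window (none expected at 1 Mbp) follow the same
  majority rule.

## Problem sizes used by the test-suite and acceptance run

The suite runs the oracle-equivalence checks at 1,000 random window
grids, 1,000 random genomes of up to 200 genes, every Mann-Whitney
partition up to a combined n of 8, and 200 random linking instances of up
to 10 fragments; planted-truth recovery uses 25 clustered genomes, one
tandem-only genotype, one generator run per violated pseudogene
criterion, and 50 seeded four-genotype datasets for the CNV split. The
acceptance script runs a five-genotype end-to-end dataset at the default
desk scale. These sizes are the package's chosen balance between coverage
and a test suite that stays fast enough to run on every change.

## Known limitations

* The collinear chainer is a greedy score-ordered extractor; pathological
  overlapping-chain layouts can differ from a global optimum, though not
  on the planted-segment geometries the generator produces.
* Clustering significance is not assessed (no null model is defined for
  window clusters), and gene-distance-based clustering is out of scope.
* Processed (retrotransposed) and duplicated pseudogenes are not
  distinguished; poly-A, intron-loss and synteny analyses of pseudogene
  origin are future work.
* Phenotype association is a scoring utility (susceptible = 1 … tolerant
  = resistant = 4; mean ≤ 2 susceptible, ≥ 3 resistant), not a genetic
  association framework.
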