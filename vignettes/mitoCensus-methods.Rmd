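---
title: "Comparative accounting of fungal mitogenomes with mitoCensus"
author: "mitoCensus authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative accounting of fungal mitogenomes with mitoCensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoCensus)
```

## The problem

Fungal mitochondrial genomes (mitogenomes) are small — roughly 12 to
270 kbp — but extraordinarily plastic. A conserved backbone of fourteen
protein-coding genes (*atp6/8/9*, *cob*, *cox1–3*, *nad1–6*, *nad4L*), two
rRNA genes (*rns*, *rnl*) and an optional ribosomal protein (*rps3*) is
embedded in a variable matrix of accessory elements: self-splicing group I
and II introns, homing endonuclease genes (HEGs, families LAGLIDADG,
GIY-YIG and rarely H-N-H) that frequently nest inside those introns,
unassigned ORFs (uORFs), and plasmid-derived DNA/RNA polymerase genes
(*dpo*/*rpo*). Comparative questions about this plasticity — how much of a
genome is genic, how accessory load scales with genome size, how often HEGs
sit inside introns, how similar deposited genomes are to one another —
reduce to a fairly small set of operations that this package implements as
reusable, tested components:

1. reading annotations and sequences (five-column feature tables, a GFF3
   subset, FASTA, metadata);
2. circular-aware interval arithmetic for genic/intergenic length
   accounting by overlap removal;
3. feature classification into the categories above, including the
   uORF triage decision tree;
4. pairwise local alignment and two identity definitions (per-HSP identity
   and the shorter-sequence clustering identity);
5. greedy redundancy clustering and an all-vs-all similarity network under
   the longest-continuous-alignment rule;
6. the summary statistics used downstream (Pearson correlations with
   t-based p-values, Wilcoxon rank-sum comparisons, patristic distance
   matrices from trees);
7. a synthetic annotated-mitogenome generator with planted ground truth,
   so that every stage can be validated end-to-end without downloads.

## Coordinates and circularity

Files use 1-based inclusive coordinates (the GenBank/Mfannot convention);
internally all interval arithmetic is 0-based half-open, which makes length
algebra unambiguous. A feature on a circular genome may wrap the
replication origin; in the five-column table dialect this is encoded as
`start > end` in one row, and in the GFF3 dialect as `end` beyond the
genome length (the usual convention for circular replicons). Wrapping
features are split internally into their two arcs.

`featureIntervals()` projects features of any strand onto a single axis,
splits wraps, and merges overlapping or adjacent segments
(`IRanges::reduce`); `coveredLength()` of the result is the *final genic
length* after overlap removal, and `intergenicLength()` is its complement.
Overlap statistics between two categories come in two explicit modes,
because "A lies within B" and "A overlaps B" are different claims:
`overlapReport()` counts A features sharing at least one base with the
union of B (*any-overlap*) and A features fully contained in that union
(*within*). Each A feature counts once however many B features it touches,
and dataset-level fractions are pooled over summed counts, not averaged
per genome. These choices are testable: the suite checks all four
operations against a per-base boolean-array brute force on a thousand
random genomes of both topologies, and checks that every statistic is
invariant under rotation of the circular origin.

## Classification and the uORF triage

Feature categories are assigned with a fixed precedence:

1. a name resolving (case-insensitively, through a synonym table) to a
   core gene, rRNA, *rps3* or tRNA label;
2. a name marking an intron, with the class (IA, IB, IC1, IC2, ID, II)
   parsed from the name — intron classes come from annotation, not from
   secondary-structure inference;
3. identity triage: a local-alignment identity strictly above 0.80 to a
   reference panel (HEG, *dpo*, *rpo*) assigns that class, highest
   identity winning; an exact tie demotes to `other` with a warning;
4. a protein-domain hit of a homing-endonuclease family (accepted at
   e-value ≤ 0.01 by default; the threshold is configurable because the
   original procedure states none) gives HEG with the family subtype;
5. any other accepted domain hit gives `domain_orf`;
6. an ORF with no evidence of any kind is a uORF.

Core-gene presence uses the absence rule: a gene is present when annotated
by name *or* when a local alignment of the genome against the gene's
reference set reaches identity strictly above 0.50. We additionally
require that the HSP cover at least half of the reference length. This
coverage requirement is an extension of the stated rule: without it, a
20 bp chance HSP at 60% identity in AT-rich sequence would "rescue" genes
that are genuinely absent. With it, the planted-truth tests recover the
exact presence/absence matrix at dropout rates 0, 0.3 and 1.

## Alignment

The scoring scheme is BLASTn-like: match +1, mismatch −2, and affine gaps
costing −5 − 2k for a gap of k bases. Two code paths produce HSPs:

* **Exact** (both sequences ≤ 2,000 bp): iterated full Smith–Waterman
  (affine-gap, banded C++ kernel run unbanded) with masking of reported
  segments, giving locally optimal non-overlapping HSPs.
* **Seeded** (longer sequences): shared 11-mers are collected with a
  word-frequency cap and a low-complexity filter — AT-rich mitogenome
  background otherwise floods the seed list with near-homopolymer words —
  then grouped into clusters by diagonal and position. Each cluster with
  at least two seeds (a two-hit rule) defines a window and a diagonal
  band, centred on the densest diagonal core of its seeds, inside which
  the *same exact DP kernel* runs. Clusters are extended in order of seed
  support under a total DP cell budget, so pathological seed scatter
  cannot make a comparison arbitrarily slow. We chose windowed exact DP
  over a classical X-drop extension because it is equally fast at these
  genome sizes and directly comparable, cell for cell, with the
  full-matrix oracle used in the tests.

Both strands are always searched. HSPs are reported sorted by alignment
length (ties: more matches, then smaller query start), because the network
rule below consumes the *longest continuous alignment*, not the
best-scoring one; the score-maximal HSP is still trivially available from
the same table. Identity comes in two definitions: `hspIdentity()` is
identical columns over alignment columns of one HSP; `clusteringIdentity()`
is identical columns of the best local alignment divided by the length of
the shorter sequence (the global-identity convention of greedy clustering
tools, under which an exact substring scores 1.0 against its parent).

## Redundancy clustering and the similarity network

`greedyCluster()` follows greedy incremental clustering semantics: genomes
sorted by length descending (ties by id) each join the first cluster whose
*representative* they match at or above the threshold (default 0.90), else
found a new cluster. Members are compared only against representatives —
the documented divergence risk of that convention is real: two copies each
at 0.95 identity to a common ancestor sit near 0.95² ≈ 0.90 to each other,
so which member becomes representative can decide a borderline join. The
synthetic family planter therefore keeps the ancestor strictly longest, so
within-family identity is always identity-to-ancestor. A shared-word
prefilter skips alignments for pairs whose distinct shared 11-mer count is
far below what any above-threshold alignment would retain.

`buildNetwork()` aligns every unordered pair and emits at most one
undirected edge carrying the identity of the length-maximal HSP — when a
pair aligns in several segments, only the longest continuous alignment
counts. Edge filters (`minIdentity`, `minHspLen`) default to off. One
practical note reflected in the tests: genomes that share conserved core
genes always produce short moderately-high-identity HSPs, so separating
planted families in a network needs the HSP length filter, not an identity
cut alone — with `minIdentity = 0.7, minHspLen = 400` the connected
components of a planted two-family dataset equal the families exactly.
`networkComponents()` (igraph) includes isolated genomes as singletons.

## Statistics

`pearsonCorrelation()` returns the product-moment coefficient with the
two-sided p-value from the t transform with n − 2 degrees of freedom, with
an optional log10 transform for the uORF-length correlations (the only
place the original analysis states a log scale). `wilcoxonRankSum()` is
two-sided, exact by enumeration when the combined sample size is at most
12 with no ties, and otherwise uses the normal approximation with midranks,
tie correction and continuity correction; the exact path is verified
against full enumeration of all rank assignments, and the approximate path
by a 1,000-replicate null simulation whose rejection rate at α = 0.05 must
fall in [0.03, 0.07]. `patristicMatrix()` computes leaf-to-leaf path-length
sums from newick trees with mandatory branch lengths (trees are inputs;
phylogenetic inference is out of scope). All tests are two-sided
throughout, since no direction is ever pre-specified.

## The synthetic-data generator

`generateDataset()` builds annotated genomes whose defaults emulate the
regimes reported for curated fungal mitogenome collections, scaled down
10× in length so that exhaustive alignment oracles stay fast:

* genome lengths lognormal (median ≈ 8 kbp, truncated to 2.4–27.2 kbp).
  The lower bound is 2.4 kbp rather than 1.2 kbp because a full core
  complement at this scale occupies ≈ 2 kbp, and the pipeline's
  completeness filter removes genomes under 2 kbp; the real 12 kbp
  minimum belongs to a genome lacking nine core genes. Element lengths
  and the length distribution are balanced so the genic fraction sits
  near 0.6, as in real fungal mitogenomes — a genome must always be able
  to hold its planted features, and if feature loads dominated the drawn
  lengths the length distribution would degenerate into a deterministic
  function of the loads;
* ≈ 5% linear topologies; genetic codes mixed with code 4 dominant (62%),
  then 1, 3 and 16; GC targets normal around 25% (clamped per genome to
  the range achievable around its conserved genes) and realized *exactly*
  by constructing the intergenic background with the exact base counts —
  the suite asserts |GC − target| ≤ 0.02;
* per-genome Poisson counts of HEGs (mean 8, family mix ≈ 78% LAGLIDADG /
  22% GIY-YIG / a trace of H-N-H) and uORFs (mean 8.2). Each HEG is
  nested inside an intron with probability 0.45 and free-standing
  otherwise; an embedded HEG founds its own host intron (HEG-bearing
  introns are mostly ORF in real mitogenomes), and HEG-free introns
  follow a Poisson whose mean keeps the total intron mean at 8.
  *dpo*/*rpo* copies are planted as mutated copies of the synthetic
  reference panel at 0.90 identity so the >0.80 identity triage genuinely
  exercises the alignment path;
* a coupling coefficient ties accessory counts to genome length
  (counts scale as exp(c·z − c²/2) with z the standardized log-length),
  which reproduces the positive length-versus-accessory-load correlations
  qualitatively; the correlation between intron and HEG totals exceeds
  either when embedding is high, because nested HEG bases are intron
  bases;
* genomes are assembled as shuffled feature blocks separated by random
  intergenic gaps, then circularly rotated to a random origin — which is
  what makes some features wrap and keeps the interval code honest.

Feature sequences are random DNA with planted start/stop codons; no real
homology is imitated, because classification is name- and evidence-driven.
What the generator does *not* emulate: codon usage, phylogenetic
autocorrelation between genomes, repeat content beyond what random AT-rich
sequence produces, and the coupling of genetic code to lineage. Tests
passing on these data therefore validate the *accounting machinery*
exactly, not the biological realism of any particular number.

`mutateCopy()` applies events at rate 1 − target (90% substitutions, 10%
indels with geometric sizes, mean 3 bp) and remaps feature coordinates
through the indel map. For targets ≥ ~0.85 the realized clustering
identity tracks the target within ±0.03; for low targets the positive-
scoring local alignment necessarily fragments and realized identity falls
below the nominal rate — family fixtures only use the high-identity
regime, and the low regime is used only to assert separation.

## The pipeline

`runPipeline()` wires the stages in the order of the published workflow:
quality filter (minimum length 2 kbp, at most 20% N), greedy redundancy
clustering at 0.90 (the filter runs *before* all statistics; only
representatives continue), classification, presence matrix, interval
accounting and census, overlap reports, correlations, similarity network,
and a JSON manifest echoing parameters, seed and per-stage record counts.
Thresholds are strict inequalities where the source states "above".
Configuration can come from YAML via `readPipelineConfig()`.

## Problem sizes and numerical choices

The test suite and the acceptance script use deliberately modest sizes
chosen as representative working points: 1,000 random genomes (≤ 5 kbp,
≤ 40 features) for the interval oracle; 200 random pairs (≤ 500 bp) for
the alignment oracle; ten seeds of four 3-member families (2.4–9 kbp,
light accessory loads so features always fit) for clustering recovery;
n = 200 genomes for the coupling correlations; 1,000 null replicates for
the rank-sum calibration. Degenerate inputs are defined, not accidental:
empty feature lists give empty interval sets, an empty A-category yields
NA fractions (never 0), all-N sequences make GC undefined (error), a
missing branch length or duplicate leaf is an error, and zero variance
makes a correlation an error rather than NaN.

## Known limitations

* The seeded alignment path is a heuristic: HSPs far from any seed
  cluster, or beyond the cell budget in seed-poor comparisons, can be
  missed; the exact path bounds behaviour for sequences ≤ 2 kbp.
* Greedy clustering inherits the representative-only comparison semantics,
  including its order dependence for borderline pairs.
* Intron classes are taken from annotation labels; there is no structural
  classification.
* The generator's genomes are compositionally realistic but evolutionarily
  naive; correlations measured on them demonstrate that the machinery
  recovers planted structure, not that real fungi behave identically.
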