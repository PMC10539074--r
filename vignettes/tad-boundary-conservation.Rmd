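---
title: "Detecting conserved TAD boundaries across genomes with tadcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved TAD boundaries across genomes with tadcons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadcons)
```

## The problem

Topologically associating domains (TADs) partition interphase chromatin
into self-interacting blocks, and their boundaries anchor loop formation
and insulate regulatory contacts. Comparing TAD boundaries across species
asks a deceptively simple question — *is this boundary the same boundary
over there?* — that coordinate lift-over pipelines answer poorly: building
whole-genome alignment chains is expensive, and chain construction
discards duplicated regions, which is precisely where interesting boundary
evolution happens.

`tadcons` answers the question with two cheaper, complementary evidence
channels computed directly from each species' genome sequence, gene
annotation and TAD calls:

1. **Gene-anchor (synteny) channel.** Orthologous protein pairs are
   chained into collinear blocks; two boundaries are linked when an
   anchored gene pair falls inside both boundary regions.
2. **Sequence channel.** The boundary region's own sequence is aligned to
   the other genome; a long alignment landing inside a boundary region of
   the target species links the two boundaries.

Evidence from both channels, in both query/target directions, is merged
into undirected weighted *boundary pairs*; pairs across all species form
a *boundary graph* that is clustered with the Markov Cluster algorithm
(MCL). Clusters spanning every species are *conserved*, single-species
clusters are *specific*, the rest *partial*.

## From TAD calls to boundary regions

Each TAD interval contributes its two edges. Edges are expanded
symmetrically by a radius $r$ (default 20 kb, i.e. a 40 kb window, the
scale of a mammalian TAD-boundary bin; overridable globally and per
species) and overlapping or abutting windows are merged, so a dense run
of edges becomes one boundary zone whose `source_edges` counts its
support. Internally every coordinate is 0-based half-open; GFF3 input is
converted on read. Merged regions on a chromosome are disjoint by
construction, which lets a gene be assigned to at most one region
downstream.

Edge windows at chromosome ends are clipped, not dropped — telomeric
boundaries are kept.

## The synteny channel

An all-vs-all protein search seeds candidate pairs by shared amino-acid
5-mers (at least 2) and scores candidates with local Smith–Waterman under
BLOSUM62 (gap open 11, extend 1). Hits scoring below `min_score` (50) are
discarded, each gene keeps its best 5 partners (ties to the
lexicographically smallest id), and each unordered pair is reported once.

Anchors are chained into collinear blocks by dynamic programming over
gene *ranks* (ordinal position along the chromosome): anchor $j$ extends
$i$ when $0 < \Delta\text{rank}_A \le g$ and
$0 < |\Delta\text{rank}_B| \le g$ with one sign per chain
(`gap_max` $g = 25$; increasing = `same`, decreasing = `inverted`
orientation). Chains are extracted greedily by anchor count (ties to the
leftmost start) and must carry at least 4 anchors. When a block is
emitted, *all* anchors touching its genes are retired, so a gene belongs
to at most one block — but a tandem family still yields one anchor per
copy, which is how duplication-derived boundary conservation stays
visible. The suite checks emitted blocks against an exhaustive
best-chain search on instances up to 30 anchors.

A boundary pair's synteny weight sums, over supporting anchor pairs,
both gene lengths in bp.

## The sequence channel

Genome divergence is estimated first, with a MinHash sketch: the 1000
smallest 53-bit hashes of canonical 21-mers. For two sketches the Jaccard
similarity $j$ is estimated from the merged bottom sketch and converted
to the Mash distance

$$d = -\frac{1}{k}\,\ln\frac{2j}{1+j},$$

with $d = 1$ at $j = 0$ and $d = 0$ for identical sketches. The distance
selects the alignment stringency preset: $d \le 0.01$ → `asm5`,
$0.01 < d \le 0.1$ → `asm10`, $d > 0.1$ → `asm20`, mirroring the
documented divergence bands of assembly-to-assembly alignment presets
(~1%, ~5%, ~10%).

The builtin aligner finds exact 15-mer anchors between each boundary
sequence and the target genome (both strands; k-mers occurring more than
50 times in the target are skipped as repeats), groups them into
diagonal bands (tolerance 500 bp), splits a band where the target gap
exceeds 2 kb, and reports each group of at least two distinct anchors
spanning at least 200 bp as one hit. Identity is estimated as the
fraction of the query span covered by anchors — a conservative lower
bound on true identity, so the preset thresholds (asm5 0.8, asm10 0.5,
asm20 0.3) are calibrated on this anchor-coverage scale, not on percent
identity. A PAF adapter accepts an external whole-genome aligner instead.

Hits shorter than **2 kb are discarded** (strictly greater-than, the
pipeline's default `min_align_len`), suppressing spurious short matches.
A surviving hit that overlaps a target boundary region by at least 1 bp
creates a pair whose weight sums the aligned lengths. The "near the
boundary" notion is carried entirely by the radius-expanded region — no
second slack window is added, so the user-facing radius is the single
locality parameter.

## Integration, graph and clustering

For each species pair the synteny pairs (direction-free) and the two
directional sequence-pair sets are merged on the unordered boundary pair:
sequence directions are symmetrised by keeping the larger weight
(conservation is undirected; the stronger direction is the better
estimate), then channel weights add and the evidence label becomes
`both` when the channels agree. A boundary may pair with several partners
in one genome — one-to-many pairs are deliberate and carry duplications
and translocations.

The boundary graph keeps *all* boundaries as nodes, including unpaired
ones. MCL runs on the weighted adjacency matrix with self-loops set to
each node's maximum incident weight (minimum 1, damping odd-cycle
parity), alternating expansion (matrix squaring) and inflation
(entrywise power 2.0, the canonical default, then column
renormalisation), pruning entries below $10^{-5}$, until the largest
column change falls below $10^{-8}$ or 100 iterations. Clusters are read
out as connected components of the attractor-overlap structure (nodes
sharing mass in an attractor row), which guarantees a partition even
under weak convergence; isolated nodes become singleton specific
clusters, which is how per-genome specific-boundary proportions arise.
Raw bp weights are used as-is by default; `log_weights` compresses their
dynamic range when a run mixes very long and very short evidence.

Classification uses species presence: `conserved` requires at least
`conserved_min_species` species (default: all manifest species — the
strictest reading; relax it to study clade-level conservation),
`specific` is exactly one. The cluster-by-species count matrix
(phylogenomic profile) is exported as TSV and, optionally, drawn as a
heatmap via `pheatmap`.

## The synthetic clade generator

Real multi-species Hi-C compendia are too large to ship, so validation
uses a seeded simulator whose defaults are the package's study
conditions: 3 species, one 2 Mb chromosome, 200 genes (900 bp single-exon
CDS every 10 kb), 40 TADs of 45 kb tiling 0.1–1.9 Mb; per branch: 2%
substitutions, 2 inversions, 1 translocation, 1 duplication (whole-TAD
segments, breakpoints on a 5 kb grid that never splits genes), boundary
gain probability 0.1 per TAD and loss probability 0.05 per internal
edge; seed 42.

The generated manifest sets a 5 kb boundary radius — proportionate to
the 45 kb simulated TADs, and chosen so that boundary regions stay
well-separated; the pipeline-wide default stays 20 kb for real mammalian
inputs. Gains are implanted at a species-specific offset at least
10.5 kb inside a TAD, spaced so that gained regions of different species
never overlap homologous coordinates (guaranteed for up to 3 species;
beyond that the offsets tighten and occasional cross-species collisions
become possible — the generator is a test harness, not a simulator
contribution, and uses a star phylogeny for the same reason).

Ground truth maps every TAD edge to its ancestral source. Two bookkeeping
subtleties matter and are deliberate:

* a duplicated edge has **two** descendant positions (both recorded);
* an **inversion junction** carries the outer flank of one segment-end
  edge and the mirrored inner flank of the other, so both end edges are
  recorded as its sources. Scoring without this aliasing punishes the
  pipeline for correctly linking a junction to either parent group.

`evaluate_recovery()` calls a pan-conserved truth group recovered when a
single conserved-class cluster contains at least one of its descendant
boundaries from every species, and a gained boundary correctly labelled
when its cluster is specific-class.

## Numerical and degenerate-input choices

* "Longer than 2000 bp" is a strict inequality; an exact-2000 hit drops.
* TAD rows with `end <= start` are a line-numbered hard error, not a
  silent skip.
* Representative isoform = largest summed CDS, ties to the smallest mRNA
  id; genes without usable CDS are skipped with a warning; internal stop
  codons are kept (and counted in a message) so that pseudogenised or
  sloppily annotated models still participate in the homology search.
* Codons containing N translate to X; translation uses the plain
  standard table (no initiator-codon special-casing).
* MinHash hashes are the top 53 bits of a 64-bit splitmix-finalised
  hash, so values are exact in doubles.
* MCL re-seeds an all-pruned column on its diagonal rather than failing.
* Stage results are cached under `outdir/cache/` keyed by an MD5 of the
  full configuration; a rerun with the same configuration is read back
  verbatim, which also makes byte-identical outputs easy to verify.

## What the tests do and do not show

The simulator exercises every pipeline branch — substitution divergence,
inverted and translocated blocks, duplicated boundaries, species-specific
gains and losses — at desk scale (problem sizes above, about a minute end
to end on one CPU). It does not emulate repeat content, indels, assembly
gaps, annotation noise or realistic codon evolution; passing its
recovery checks demonstrates the machinery is correct, not that any
particular biological count from real compendia will be reproduced.
Parameter defaults for real data (radius 20 kb, 2 kb length filter,
inflation 2.0) follow the conventions of the tools this pipeline
re-implements and should be revisited per dataset, especially for plant
genomes with much smaller TADs.
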