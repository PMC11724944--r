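---
title: "Accounting for sequence in a path-covered pangenome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for sequence in a path-covered pangenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panledger)
```

## The problem

A pangenome graph built from many assemblies of one species collapses
shared sequence onto shared nodes: each node (GFA segment) carries a
stretch of DNA exactly once, and each assembly is a path that walks over
the nodes it contains. Questions like *"how much sequence did this
assembly add that the reference lacks?"* then become set arithmetic over
node lengths — but only if the accounting is done carefully: nodes are
shared by arbitrary subsets of assemblies, so naive per-sample sums double
count, and the order in which assemblies are credited changes their
apparent contribution.

`panledger` implements that accounting for the outputs a
Minigraph-Cactus-style pipeline produces: the graph itself (GFA v1.1 with
`P`/`W` sample paths), the multi-sample VCF of variants called against the
graph, and the MAF alignment blocks derived from the underlying HAL
alignment. A fourth module computes conventional assembly summary
statistics, and a fifth generates seeded, ground-truthed miniature
pangenomes so the whole pipeline can be validated end to end without any
external data.

## The attribution procedure

Let $V$ be the node set, $\ell(v)$ the length of node $v$, and
$C_s \subseteq V$ the set of nodes covered by any path of assembly $s$
(either orientation; multiplicity ignored — a node is one piece of
sequence no matter how often a path revisits it). With reference $r$:

1. credit the reference with $\sum_{v \in C_r} \ell(v)$ and delete $C_r$
   from every other sample's set;
2. repeatedly select the sample $s^\*$ with the largest remaining
   $\sum_{v \in C_s} \ell(v)$, record that amount as its contribution, and
   delete its nodes from all remaining sets, until every sample has been
   evaluated (samples reaching their turn with an empty set are recorded
   at 0 bp, not dropped);
3. nodes covered by no path are reported as unassigned.

The procedure conserves sequence by construction:
$\text{ref} + \sum_s \text{bp}_s + \text{unassigned} = \sum_v \ell(v)$,
and the greedy contributions are non-increasing over rounds (removing
nodes can only shrink later sets). Two properties make the result
interpretable and are asserted in the test suite rather than assumed:
when post-reference sample sets are pairwise disjoint the outcome is
independent of evaluation order, and sample-exclusive novel sequence is
always credited to its owner exactly. Ties on remaining bp are broken
lexicographically by sample name; the published description of the
procedure is silent on ties, and a deterministic rule makes runs
reproducible. The attribution operates on whole nodes: the graph's own
segmentation defines the resolution, and sub-node novelty is out of
scope.

`mean_degree` is reported as $E/N$ (edges per node), matching the
convention of the variation-graph toolkit statistics this mirrors; the
package additionally exposes $2E/N$ as `mean_incident_degree` because
"degree" in graph theory usually means incident edge ends. On the
published chicken pangenome counts ($E = 121{,}720{,}974$,
$N = 87{,}934{,}214$) the former rounds to 1.4, which is the printed
statistic.

## Variant classification

Variants carried by one sample are pulled from the multi-sample VCF the
way `bcftools view -a -s <sample>` would: a record survives iff the
sample's genotype contains a non-reference, non-missing allele index;
uncarried alternate alleles are dropped and indices renumbered. Phased
and unphased separators are treated identically; each distinct carried
allele is classified once, so a `1/2` genotype yields two
classifications. Symbolic alleles (`<DEL>`, breakends) are rejected —
the graph pipeline's VCF is sequence-resolved.

Classification is by allele length alone, with two thresholds exposed in
`classifier_config()`:

* `sv_min_delta` (default 50 bp): $|\Delta| \ge 50$ flags a structural
  variant, where $\Delta = |\text{alt}| - |\text{ref}|$. The bound is
  inclusive in both directions.
* `indel_max_len` (default 1000 bp): length-changing variants with
  $|\Delta| < 1$ kb are *indels*; at or above it they are *insertions*
  ($\Delta > 0$) or *deletions* ($\Delta < 0$).

$\Delta = 0$ gives *snv* (length 1) or *mnv*; and a length-changing pair
that still differs on both sides after anchor trimming (one shared
leading base, then the shared trailing run) is reported as *complex*,
since its length-based class would misstate a substitution entangled
with the length change. A deliberate consequence of the two-threshold
design is that a 119 bp contraction is an SV *and* an indel: the SV flag
and the class answer different questions.

## MAF census

Blocks are dropped whole when any row belongs to an excluded genome —
by default the ancestral root `Anc0`, the synthetic graph genome
`MINIGRAPH`, and the reference `GRCg7b` — and surviving blocks are
censused two ways: total bp per assembly, and a histogram of blocks by
the number of *distinct* assemblies present. Base pairs are the
`s`-line `size` field (ungapped sequence length), not alignment columns;
a genome with several rows in one block contributes all their sizes but
counts once toward multiplicity. Blocks are counted as serialized:
blocks split at the converter's chunk boundaries are not merged, so
block-frequency histograms are only comparable between files produced
with the same chunking.

## Assembly statistics

N50/L50 follow the textbook definition (sort descending, accumulate to
half the assembly size); `nx_stats()` accepts an external `total` so the
statistic can be computed from a partial length list — e.g. the 40
published chromosome-scale scaffold lengths of the KLC assembly with the
whole-assembly total of 1,023,165,347 bp, which reproduces the published
N50 of 90,511,606 bp at L50 = 4. That usage is valid exactly when every
unlisted scaffold is shorter than the crossing length (true here: the
~15 Mb of unplaced scaffolds is far below 90.5 Mb); `nx_stats()` errors
if the listed lengths cannot reach the half-way point at all. GC content
is computed over unambiguous bases only — `100·(G+C)/(A+C+G+T)`, with N
and IUPAC ambiguity codes excluded from numerator and denominator — the
convention of the standard assembly-QC tools. The published
per-chromosome table carries its own internal tension (the chromosome
lengths do not sum to the separately printed chromosome-scale total);
the package reproduces each printed value from its own inputs and makes
no attempt to reconcile them.

## The synthetic generator

`generate_pangenome()` emits a miniature pangenome in every format the
pipeline consumes — GFA, per-assembly FASTA, multi-sample VCF, MAF — all
derived from one plan, plus the plan's expected values (`truth.json`).
The design emulates what the real data look like statistically:

* a reference core split into backbone segments that every path
  traverses (shared sequence collapsing onto shared nodes);
* variant bubbles at junctions between core segments: SNV bubbles
  (1 bp reference vs alternate segment), deletions (carriers skip a
  reference segment), and insertions (carriers traverse an extra
  segment), each with a random carrier subset of the non-reference
  samples (at least one carrier; expected size set by
  `carrier_fraction`);
* sample-private insertions — the "novel sequence" each assembly brings;
* MAF decoy blocks containing `Anc0`, `MINIGRAPH` and reference rows so
  the exclusion filter is always exercised.

Bubbles occupy distinct junctions and are therefore non-overlapping and
separated by at least one core segment by construction (the generator
validates that the variant count fits the junction count instead of
re-drawing placements); nested variation is deliberately absent. Default
lengths (insertions and deletions drawn between tens of bp and 1.5 kb)
straddle both classification thresholds so insertion, deletion and indel
classes all occur. Haploid genotypes are emitted, as assembly-vs-graph
calls are; indel records use the anchor-base convention of
sequence-resolved VCFs. All randomness flows from R's default
Mersenne-Twister stream seeded once with `seed`, so identical parameters
give byte-identical files.

The generator's expected contribution ledger is computed directly from
the plan (which variant has which carriers), never by re-reading the
emitted files — `verify_bundle()` therefore compares two independent
routes to the same numbers. What the generator does *not* emulate:
repeat families, chromosome-scale sizes, sequencing error, nested or
overlapping variation, and multi-contig assemblies. Green tests
demonstrate that the accounting is correct on graphs whose structure is
known; they say nothing about, for example, how the upstream graph
builder segments real repetitive DNA.

## Problem sizes and numerical choices

The bundled validation uses pangenomes of 5 assemblies, a 6 kb core in
40 segments, and about 15 planted variants per bundle, swept over 20
seeds — small enough that each end-to-end check is near-instant, large
enough that every class, threshold boundary (49/50 and 999/1000 bp) and
code path is hit. Lengths are accounted in doubles; the quantities
involved (up to ~10^9) are exactly representable. Degenerate inputs
have defined behaviour rather than errors where a value is meaningful:
an empty graph reports mean degree 0 with a warning, a sample evaluated
with nothing left is recorded at 0 bp, and an empty FASTA yields an
empty record table. Errors are reserved for contract violations:
unknown segment references, genotype indices beyond the ALT list,
alignment rows whose declared size disagrees with their text.

## Known limitations

* P-line sample names are recovered by convention (PanSN `#`, then first
  `.`, then the whole name); assemblies named outside those conventions
  would need pre-normalized path names.
* The attribution is node-resolution: if the graph builder leaves
  near-duplicate sequence on distinct nodes, it is counted as distinct
  sequence.
* Class counts on real pipeline VCFs depend on upstream normalization
  (allele trimming, multi-allelic splitting); the classifier is
  deterministic given the records it is handed.
* `read_maf()` holds the parsed table in memory; files far beyond the
  desk scale this package targets would need chunked processing.
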