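---
title: "Methods: LCA binning, rank projection, functional trees, ordination and gene-centric assembly"
author: "lcabin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcabin)
```

This vignette is the package's own account of the models it
implements, the parameters that matter, the numerical conventions that
make results reproducible, and what the synthetic test bed does and
does not show about real data.

# Input model

The unit of input is a tabular DNA-to-protein alignment file: one row
per alignment in the standard 12-column order (query, subject, percent
identity, alignment length, mismatches, gap opens, query start/end,
subject start/end, e-value, bit score). Query coordinates are 1-based
inclusive nucleotide positions on the read; `qstart > qend` encodes a
negative-frame alignment and is normalized on input to a forward
interval plus a `reverse` flag, so the writer can reproduce the
original row bit-exactly. Rows are expected read-contiguous (all
alignments of one read in one block), which lets the binners stream
per read; a seen-set check enforces this.

Reference identity is resolved by one of three mechanisms, mirroring
how protein databases carry classification identity: a header tag
(`tax|666` anywhere in the header), a numeric-id token table, or an
accession token table queried with and without the `.version` suffix.
Resolution is pure and order-independent; an unresolvable header is a
value (`NA`), not an error, and unresolvable alignment rows are
tallied, never fatal.

## Significance filter

Binning operates only on "significant" alignments. Significance is
not part of the input format, so the gate is explicit and every value
is echoed into output headers:

| parameter            | default | meaning                                         |
|----------------------|---------|-------------------------------------------------|
| `minScore`           | 50      | minimum bit score                                |
| `maxExpected`        | 0.01    | maximum e-value                                  |
| `topPercent`         | 10      | keep scores within 10% of the best *surviving* score |
| `minPercentIdentity` | 0       | minimum percent identity (off)                   |

Applying `topPercent` after the absolute gates, relative to the best
surviving score, makes the two gates order-independent in effect and
the whole filter idempotent — a property the test suite pins.

# Taxonomic binning

The taxonomy is a rooted tree with ranks from a fixed nine-step
vocabulary (root, domain, phylum, class, order, family, genus,
species, strain); any other rank string becomes `norank`, which is
transparent to rank queries. The root is the unique node whose parent
is itself. Validity checks enforce acyclicity and that ranks never
get shallower with depth.

**Naive LCA.** A read is assigned to the lowest common ancestor of
the taxa of all its significant alignments. References mapped above
species rank participate at their own rank: LCA is rank-agnostic, and
requiring species-resolved references would discard perfectly usable
genus- or family-level mappings.

**Weighted LCA.** Phase 1 scans the whole sample once and weights
each reference by the number of reads supporting it unambiguously: a
read contributes to the weight of every reference it aligns to iff all
its resolved references share one species assignment, where a
reference's species assignment is its species-rank ancestor, or its
own taxon when no species ancestor exists (the least destructive
completion for above-species references). References left at weight 0
are floored to 1; without the floor, reads aligning only to ambiguous
references would carry zero total weight and be unplaceable. Phase 2
places each read on the deepest node whose subtree covers at least
`coverage` (default 0.75) of the read's total reference weight. For
`coverage > 0.5` the qualifying nodes form a chain by a pigeonhole
argument, so the deepest one is unique; the implementation asserts the
chain during traversal and refuses `coverage <= 0.5`. Whether a read
should weight all of its surviving references or only the best-scoring
ones is a genuinely open choice; this implementation weights all
surviving alignments, and the tests pin that behavior.

**Min-support filter.** Off by default (`minSupport = 1`). When
enabled, nodes whose on-or-below count is below
`max(minSupport, ceiling(minSupportPercent * assigned))` have their
directly assigned reads promoted to the parent, deepest-first, which
cascades naturally: a node can only fail the threshold after all of
its descendants' reads have already collapsed into it. The filter is
applied before projection; applying it after would re-spread counts
the filter just consolidated.

## Rank projection

Profiles are reported at one fixed rank (default `species`, the rank
used for species-level sample profiles). Counts below the target rank
roll up to their ancestor at that rank. Counts above it are pushed
down iteratively: a node's count is split among those children that
carry reads on or below them *and* lead to the target rank, in
proportion to their on-or-below counts. Fractional shares are
integerized by largest remainder with fraction ties going to the
smaller taxon id — the only convention under which the split is
simultaneously proportional, integral, exactly conservative and
deterministic. Reads on a node with no descendant at the target rank
go to an explicit `UNRESOLVED` bin; reads that never had a resolvable
alignment occupy `UNASSIGNED`. With both bins included, profile
counts sum exactly to the sample's read count, and the test suite
checks this as an integer identity on random tree/count
configurations.

# Functional classification

Functional hierarchies are generic rooted forests; every node id is
binnable, inner nodes included, and reads are assigned best-bitscore
first with ties broken by input order. Content for specific systems
(subsystem or orthologous-group catalogs) is deliberately not shipped:
those are external, versioned resources; the package ships the loader
and the tree semantics.

The InterPro-to-GO-slim builder is the one tree constructed by rule
rather than loaded. Per family and per GO domain, the family's GO
annotations are reduced (through a supplied GO-to-slim ancestry map)
to slim terms: one slim term places the family under it, several place
it under a lazily created `Other` child of the domain node, none at
all places it under `Unclassified`. A family therefore occurs at most
three times, at most once per domain. The ancestry map is an input
rather than being derived from the full GO graph — parsing the
ontology would add a heavyweight dependency for what is, for this
structure, a lookup table; the synthetic fixtures fabricate consistent
maps. `Other` node ids are derived as `<domain>:Other` and families
are processed in sorted accession order, so rebuilding from identical
inputs is bit-identical. Roll-up counts a multi-placed family fully at
each placement (a family's node shows all of its reads under every
domain it maps to); sums over tier-1 nodes can then exceed the number
of classified reads, which the output header states.

# Comparison, distances, ordination

Merging profiles takes the union of class ids with zeros off-support
and merges metadata by attribute name, `NA` for gaps. Normalization
(scale every sample to the smallest classified total) is an explicit,
idempotent step — distances always operate on the document as given,
never on hidden normalized state. The core biome uses an explicit
detection threshold (`detectionMin`, default count 1) because
"present in a sample" is otherwise undefined for count data.

Bray-Curtis and Euclidean distances are the textbook formulas;
Jensen-Shannon uses the natural logarithm with `0 log 0 = 0` and
reports the square root of the divergence, so disjoint samples sit at
`sqrt(ln 2) ≈ 0.8326`. PCoA is classical scaling: double-center the
squared distances, eigendecompose, scale eigenvectors by the square
roots of the positive eigenvalues. Axis signs are fixed by forcing the
largest-magnitude coordinate on each axis positive, which makes
coordinates reproducible across eigensolvers. Negative eigenvalues
(expected for non-Euclidean dissimilarities such as Bray-Curtis) are
excluded from the explained-fraction denominator with a warning;
requested axes beyond the positive spectrum are truncated, likewise
with a warning. On Euclidean input the embedding equals a PCA of the
centered data, and the tests verify both distance reconstruction (to
1e-9) and axis-wise collinearity with a PCA oracle.

Bi-plot vectors need a magnitude convention beyond "direction of
steepest increase": here each class's vector component on axis *j* is
the Pearson correlation between the class's per-sample relative
abundances and the axis-*j* coordinates, scaled by the class's share
of total standard deviation; classes are ranked by vector length, ties
by ascending id, top `nTop = 5` returned by default (the usual
top-five display). Using relative abundances makes the ranking
invariant under per-sample rescaling. Zero-variance classes are
excluded — their correlation is undefined and their direction
meaningless. Tri-plots apply the same machinery to numeric metadata
attributes, skipping non-numeric ones with a message.

# Gene-centric assembly

The assembler works per class: anchor, infer, verify, merge.
Anchoring picks each read's best-bitscore alignment to a reference in
the class (ties to the lexicographically smaller reference id) and
reverse-complements negative-frame reads so all anchors are forward.
Two reads on the same reference with overlapping amino-acid intervals
imply a relative DNA offset (`3 * Δref_start − Δread_offset`); the
implied overlap is then verified base-by-base over the full
overlapping span. The defaults — 20 nt minimum overlap, 0.98 minimum
identity — are chosen so that haplotypes a few percent apart cannot
form cross-strain edges over typical overlap spans, which is what
keeps contigs strain-pure. Alignments whose nucleotide span is not
three times their amino-acid span contain frameshifts; they are
anchored but excluded from overlap inference, since an internal indel
makes the implied shift unreliable. Merging is greedy over edges in
descending (overlap length, identity) order with a union-find over
read placements; an edge inconsistent with already-fixed placements
(shift tolerance 0 nt) is skipped. Consensus is per-column majority
with ties resolved by the smallest covering read id; singletons are
never emitted and contigs shorter than `minLength = 200` nt are
dropped. All tie-breaks being deterministic, identical inputs yield
byte-identical contig FASTA. Whether overlaps should be merged across
different reference proteins of the same family is left open; this
implementation partitions strictly by reference, which can split a
gene whose reads anchor to different homologs.

# The synthetic world

The generator exists so every component can be tested against known
truth without any database download. It emulates: a balanced ranked
taxonomy; gene sequences with a two-level divergence structure
(default 0.20 between genus ancestors within a phylum, 0.05 between
sibling species — roughly the protein-identity structure of
congeneric bacteria; the first child at each level inherits its
ancestor unchanged, so the stated rates are pairwise sibling
divergences); reference proteins as exact translations; uniform or
abundance-weighted shotgun reads on both strands with per-base
substitution errors; and *oracle* alignments computed by exact codon
comparison at the known sampling offset (match +2 / mismatch −1 on
aligned amino acids), with decoy rows against same-genus or same-phylum
homologs. Everything is a pure function of parameters and seed.

It does not emulate: indels or quality-dependent errors, alignment
heuristics (every emitted row is the truth-optimal local alignment),
horizontal transfer, shared genes between unrelated taxa, uneven gene
content, or database incompleteness. Passing tests therefore
demonstrate algorithmic correctness — LCA equals its oracle,
projection conserves counts, contigs reconstruct their gene — not
robustness to aligner artifacts on real data.

Default problem sizes keep the whole suite and the acceptance script
in the minutes range: worlds of at most a few dozen taxa, samples of
hundreds to a few thousand reads, genes of 300–600 nt, 500 random
taxonomies (≤ 200 nodes) for the LCA oracle sweep and 200 random
configurations for the conservation sweep.

# Known limitations

* Long reads: the binners treat a read as one unit; interval-based
  assignment of long reads spanning several genes is out of scope.
* Paired-end information is unused in both binning and assembly.
* The weighted-LCA weight definition (all surviving alignments, not
  best-only) and the bi-plot magnitude convention are documented
  choices among defensible alternatives; both are pinned by tests so
  a deliberate change shows up as a diff.
* Profiles are plain indexed text; there is no compressed binary
  container, and no server mode — the package targets scripted batch
  analysis.
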