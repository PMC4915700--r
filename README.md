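# lcabin

Taxonomic and functional binning of shotgun-metagenome reads from
tabular DNA-to-protein alignments.

Shotgun microbiome studies compare millions of reads against a protein
reference database (DIAMOND/BLASTX style, `--outfmt 6`) and then ask
two questions: *which organisms are present* and *which genes are
present*. `lcabin` implements the batch side of that analysis for R
users: it parses the 12-column tabular alignment format, assigns every
read to a node of an NCBI-style taxonomy or of a functional hierarchy,
turns read-level assignments into fixed-rank abundance profiles,
compares many samples with their metadata, ordinates them, and
assembles the reads of any single taxon or gene family into contigs.
A fully labeled synthetic-world generator makes every step testable
without downloading any reference database.

## What it computes

**Naive LCA binning.** Each read *R* with significant alignments to
references with taxa *t1..tk* is assigned to the lowest common
ancestor `LCA({t1..tk})`. Reads hitting widely conserved genes land on
high ranks; reads hitting clade-specific genes land near the leaves.

**Weighted LCA profiling.** Two phases. Phase 1 gives every reference
*S* a weight: the number of reads aligning only to *S* or to other
references with the same species assignment; references never weighted
this way are floored at 1. Phase 2 places each read on the lowest
taxonomy node *u* whose subtree holds at least a fraction *c* (default
0.75) of the total weight of the read's references. Reads ambiguous
between a dominant and a rare sibling species are thereby recovered to
the dominant one, which is what makes the profile more specific than
the naive LCA.

**Rank projection.** Read counts spread across all ranks are converted
to a profile at one rank *H*: counts below *H* roll up to their
ancestor in *H*; counts above *H* are pushed down the tree,
apportioned among children in proportion to the reads already on or
below each child (largest-remainder integerization, ties to the
smaller taxon id), so the integer total is conserved exactly.

**Functional trees.** A generic node/parent/label hierarchy loader
(SEED- or eggNOG-style), plus a builder for an InterPro-to-GO-slim
tree: three GO domain roots and an "Unclassified" catch-all, GO-slim
terms as the second tier, and InterPro families as leaves — under
their slim term when a domain maps to exactly one, under the domain's
"Other" node when it maps to several, at most once per domain and at
most three times overall.

**Comparison & ecology.** Profiles merge into a classes x samples
document with merged metadata (CSV, `#SampleID` first column);
normalization to the smallest sample, total and core biome, grouping
by metadata attribute; Bray-Curtis, Jensen-Shannon (natural log,
square-root distance) and Euclidean distances; classical PCoA with a
deterministic sign convention (Euclidean input reproduces PCA);
bi-plot and tri-plot vectors ranking the classes / numeric metadata
attributes that correlate most with the ordination axes; Shannon,
Simpson and richness alpha diversity.

**Gene-centric assembly.** For one taxonomic or functional class, each
read is anchored on its best reference protein, protein coordinates
imply exact DNA offsets between reads on the same reference, implied
overlaps are verified base-by-base (defaults: >= 20 nt, >= 98%
identity), and greedily merged chains yield per-column majority-vote
consensus contigs — strain haplotypes stay separate because
cross-strain overlaps fail the identity gate.

## Worked example

```r
library(lcabin)

world <- makeWorld(nPhyla = 2, nGeneraPerPhylum = 2, nSpeciesPerGenus = 2,
                   genesPerSpecies = 3, geneLen = 300, seed = 7)
world
#> SyntheticWorld: 15 taxa, 8 species genomes, 24 reference proteins (seed 7)

# skewed community: the first species of each genus dominates 9:1
abundance <- setNames(rep(c(9, 1), 4), names(worldGenomes(world)))
sim <- simulateReads(world, nReads = 400, readLen = 100,
                     errorRate = 0.02, seed = 11, abundance = abundance)
aln <- emitAlignments(world, sim, decoyPolicy = "same-genus")

profile <- binSample(aln, worldTaxonomy(world), worldTaxMap(world),
                     sampleName = "demo", algorithm = "weighted")
profile
#> SampleProfile 'demo' (Taxonomy): 8 classes, 400 reads
head(sort(profile@counts, decreasing = TRUE), 5)
#> 1006 1000 1004 1002 1001
#>   99   98   94   90    7
alphaDiversity(profile, "shannon")
#> [1] 1.555522
```

The four dominant species (taxon ids 1000, 1002, 1004, 1006) absorb
~95% of the reads, matching the 9:1 simulation skew. Scoring
assignments against the simulation truth table shows why the weighted
variant exists: on this decoy-laden sample the naive LCA places 69% of
reads on their true species (the rest stall on the genus), the
weighted LCA 97%.

The same pipeline is scriptable from a shell via the thin CLI wrapper
(`inst/exec/lcabin`): `synth`, `bin`, `compare`, `pcoa`, `assemble`,
`classify-tree`. Every output starts with `#key=value` provenance
headers recording the tool version and the full parameter set.

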