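#' @import methods
#' @importFrom stats cor sd setNames
#' @importFrom utils head tail
NULL

#' Ordered taxonomic rank vocabulary
#'
#' The fixed major-rank ladder used for rank queries and fixed-rank
#' projection. Rank strings outside this vocabulary are mapped to
#' `"norank"`, which is transparent to rank queries: `norank` nodes sit
#' between major ranks without participating in them.
#'
#' @return Character vector of rank names, ordered root-to-leaf.
#' @export
#' @examples
#' taxRanks()
taxRanks <- function() {
  c("root", "domain", "phylum", "class", "order", "family",
    "genus", "species", "strain", "norank")
}

.MAJOR_RANKS <- c("root", "domain", "phylum", "class", "order", "family",
                  "genus", "species", "strain")

#' Sentinel class id for reads with no resolvable assignment
#' @export
UNASSIGNED <- "UNASSIGNED"

#' Sentinel class id for reads that cannot be placed at the target rank
#' @export
UNRESOLVED <- "UNRESOLVED"

#' Taxonomy: a rooted, ranked tree of taxon nodes
#'
#' In-memory model of an NCBI-style taxonomy. Nodes are stored as
#' parallel vectors; the root is the unique node whose parent id equals
#' its own id (NCBI dump convention, node 1). Depths are precomputed so
#' that LCA and rank queries are O(path length).
#'
#' @slot ids integer taxon ids, one per node.
#' @slot parent integer parent ids, parallel to `ids`; the root points
#'   to itself.
#' @slot rank character ranks from [taxRanks()], parallel to `ids`.
#' @slot name character scientific names, parallel to `ids`.
#' @slot children named list (by taxon id) of ascending-sorted child id
#'   vectors.
#' @slot depth integer depth of each node (root = 0), parallel to `ids`.
#' @slot rootId integer id of the root node.
#' @export
setClass("Taxonomy",
  representation(
    ids = "integer",
    parent = "integer",
    rank = "character",
    name = "character",
    children = "list",
    depth = "integer",
    rootId = "integer"
  )
)

setValidity("Taxonomy", function(object) {
  n <- length(object@ids)
  if (n == 0L) return("taxonomy must contain at least a root node")
  if (anyDuplicated(object@ids)) {
    return(sprintf("duplicated taxon_id: %d",
                   object@ids[anyDuplicated(object@ids)]))
  }
  if (length(object@parent) != n || length(object@rank) != n ||
      length(object@name) != n || length(object@depth) != n) {
    return("parallel slots have unequal lengths")
  }
  roots <- object@ids[object@parent == object@ids]
  if (length(roots) != 1L) {
    return(sprintf("expected exactly one root (parent_id == taxon_id), found %d",
                   length(roots)))
  }
  if (roots != object@rootId) return("rootId slot disagrees with parent vector")
  pidx <- match(object@parent, object@ids)
  if (anyNA(pidx)) {
    bad <- object@parent[is.na(pidx)][1L]
    return(sprintf("unknown parent id: %d", bad))
  }
  # depth consistency doubles as an acyclicity check
  rooti <- match(roots, object@ids)
  expected <- object@depth[pidx] + 1L
  expected[rooti] <- 0L
  if (!identical(expected, object@depth)) return("depth slot inconsistent with parents")
  # ranks never increase in depth order along root-to-leaf paths
  ord <- match(object@rank, .MAJOR_RANKS)          # NA for norank
  pord <- ord[pidx]
  bad <- which(!is.na(ord) & object@ids != roots &
                 vapply(seq_len(n), function(i) {
                   j <- pidx[i]
                   while (object@ids[j] != roots) {
                     if (!is.na(ord[j])) return(ord[j] >= ord[i])
                     j <- match(object@parent[j], object@ids)
                   }
                   FALSE
                 }, logical(1)))
  if (length(bad)) {
    return(sprintf("rank ordering violated at taxon %d (%s below an equal-or-deeper rank)",
                   object@ids[bad[1L]], object@rank[bad[1L]]))
  }
  TRUE
})

#' Reference-to-class resolution map
#'
#' Carrier for the three identifier-resolution mechanisms used to map a
#' reference sequence header to a taxonomic or functional class:
#' a classification tag embedded in the header (e.g. `tax|666`), a
#' numeric-id lookup table, or an accession lookup table (queried both
#' with and without a trailing `.version`).
#'
#' @slot mode one of `"tag"`, `"id"`, `"accession"`.
#' @slot tag character tag scanned for in `tag` mode (default `"tax"`).
#' @slot table named character vector mapping keys to class ids
#'   (empty in `tag` mode).
#' @export
setClass("RefClassMap",
  representation(mode = "character", tag = "character", table = "character")
)

setValidity("RefClassMap", function(object) {
  if (!object@mode %in% c("tag", "id", "accession")) {
    return(sprintf("unknown mode '%s'", object@mode))
  }
  if (object@mode == "tag" && !nzchar(object@tag)) return("tag mode requires a tag")
  if (object@mode != "tag" && length(object@table) &&
      is.null(names(object@table))) {
    return("table modes require a named lookup table")
  }
  TRUE
})

#' Per-sample class count profile
#'
#' Counts of reads per class (taxon id or functional class id) for one
#' sample, together with the parameters that produced it. After
#' fixed-rank projection the counts, including the `UNASSIGNED` bin, sum
#' exactly to `totalReads`.
#'
#' @slot sampleName sample identifier.
#' @slot classificationName name of the classification binned against
#'   (e.g. `"Taxonomy"`, `"InterPro2GO"`).
#' @slot counts named numeric vector, class id -> count.
#' @slot totalReads integer number of reads in the sample.
#' @slot parameters named list of all thresholds/settings used.
#' @export
setClass("SampleProfile",
  representation(
    sampleName = "character",
    classificationName = "character",
    counts = "numeric",
    totalReads = "integer",
    parameters = "list"
  )
)

setValidity("SampleProfile", function(object) {
  if (length(object@counts) && is.null(names(object@counts))) {
    return("counts must be named by class id")
  }
  if (any(object@counts < 0)) return("negative counts")
  TRUE
})

#' Functional classification tree
#'
#' A generic rooted forest of functional classes (GO-slim/InterPro,
#' SEED-like subsystems, eggNOG-like orthologous groups). Reads are
#' binned by external payload id; a payload id may be attached to more
#' than one node (an InterPro family occurs at most once below each GO
#' domain), in which case roll-up counts it fully at every placement.
#'
#' @slot name classification name.
#' @slot nodeId character node ids.
#' @slot parentId character parent node ids; `NA` for roots.
#' @slot label character node labels, parallel to `nodeId`.
#' @slot roots character ids of the tier-1 nodes, in display order.
#' @slot payload named list: external id -> character vector of node
#'   ids carrying it.
#' @export
setClass("ClassificationTree",
  representation(
    name = "character",
    nodeId = "character",
    parentId = "character",
    label = "character",
    roots = "character",
    payload = "list"
  )
)

setValidity("ClassificationTree", function(object) {
  n <- length(object@nodeId)
  if (anyDuplicated(object@nodeId)) {
    return(sprintf("duplicate class_id '%s'",
                   object@nodeId[anyDuplicated(object@nodeId)]))
  }
  if (length(object@parentId) != n || length(object@label) != n) {
    return("parallel node slots have unequal lengths")
  }
  isRoot <- is.na(object@parentId)
  if (!setequal(object@nodeId[isRoot], object@roots)) {
    return("roots slot disagrees with NA parents")
  }
  known <- object@parentId[!isRoot] %in% object@nodeId
  if (!all(known)) {
    return(sprintf("orphan parent id '%s'", object@parentId[!isRoot][!known][1L]))
  }
  for (ids in object@payload) {
    if (!all(ids %in% object@nodeId)) return("payload refers to unknown node")
  }
  TRUE
})

#' Multi-sample comparison document
#'
#' A class-by-sample count matrix over the union of classes observed in
#' the merged samples, plus a merged metadata table. Cells absent from
#' any input profile are zero.
#'
#' @slot samples ordered sample names.
#' @slot classificationName shared classification of all samples.
#' @slot matrix numeric matrix, classes (rows, named) x samples (columns).
#' @slot normalization `"none"` or `"to-smallest"`.
#' @slot metadata data.frame of sample attributes, rownames = samples.
#' @slot parameters named list of per-sample parameter sets.
#' @export
setClass("ComparisonDocument",
  representation(
    samples = "character",
    classificationName = "character",
    matrix = "matrix",
    normalization = "character",
    metadata = "data.frame",
    parameters = "list"
  )
)

setValidity("ComparisonDocument", function(object) {
  if (anyDuplicated(object@samples)) {
    return(sprintf("duplicate sample name '%s'",
                   object@samples[anyDuplicated(object@samples)]))
  }
  if (!identical(colnames(object@matrix), object@samples)) {
    return("matrix columns must equal samples")
  }
  if (!object@normalization %in% c("none", "to-smallest")) {
    return("normalization must be 'none' or 'to-smallest'")
  }
  if (nrow(object@metadata) &&
      !all(rownames(object@metadata) %in% object@samples)) {
    return("metadata rows must be a subset of document samples")
  }
  TRUE
})

#' Sample distance matrix
#'
#' @slot labels ordered sample names.
#' @slot values symmetric non-negative matrix with exact zero diagonal.
#' @export
setClass("DistanceMatrix",
  representation(labels = "character", values = "matrix")
)

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  if (nrow(v) != length(object@labels) || ncol(v) != length(object@labels)) {
    return("matrix dimensions disagree with labels")
  }
  if (any(diag(v) != 0)) return("diagonal must be exactly zero")
  if (max(abs(v - t(v))) > 1e-12) return("matrix not symmetric within 1e-12")
  if (any(v < 0)) return("negative distances")
  TRUE
})

#' Principal coordinate ordination
#'
#' @slot coordinates samples x k coordinate matrix (rownames = samples).
#' @slot eigenvalues all eigenvalues, descending.
#' @slot fractionExplained per retained axis, fraction of the
#'   positive-eigenvalue total.
#' @export
setClass("Ordination",
  representation(
    coordinates = "matrix",
    eigenvalues = "numeric",
    fractionExplained = "numeric"
  )
)

setValidity("Ordination", function(object) {
  if (is.unsorted(rev(object@eigenvalues))) return("eigenvalues must be descending")
  if (ncol(object@coordinates) > sum(object@eigenvalues > 0)) {
    return("more axes than positive eigenvalues")
  }
  TRUE
})

#' Read overlap graph for gene-centric assembly
#'
#' Reads anchored to a common reference protein are vertices; verified
#' DNA overlaps implied by the protein coordinates are edges.
#'
#' @slot reads data.frame of anchored reads (read_id, dna, ref_id,
#'   ref_start, ref_end, read_offset, aln_len).
#' @slot edges data.frame of verified overlaps (u, v, shift,
#'   overlap_len, identity) where `shift` is the nucleotide offset of
#'   v's read start relative to u's.
#' @slot minOverlap integer minimum verified overlap (nt).
#' @slot minIdentity minimum overlap identity fraction.
#' @export
setClass("OverlapGraph",
  representation(
    reads = "data.frame",
    edges = "data.frame",
    minOverlap = "integer",
    minIdentity = "numeric"
  )
)

setValidity("OverlapGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$overlap_len < object@minOverlap)) return("edge below minimum overlap")
    if (any(e$identity < object@minIdentity)) return("edge below minimum identity")
    ru <- object@reads$ref_id[match(e$u, object@reads$read_id)]
    rv <- object@reads$ref_id[match(e$v, object@reads$read_id)]
    if (any(ru != rv)) return("edge joins reads anchored to different references")
  }
  TRUE
})

#' Assembled consensus contig
#'
#' @slot contigId contig identifier.
#' @slot consensus consensus nucleotide sequence.
#' @slot members data.frame (read_id, start) giving each member read's
#'   1-based placement on the consensus.
#' @slot coverage integer per-base read depth along the consensus.
#' @export
setClass("Contig",
  representation(
    contigId = "character",
    consensus = "character",
    members = "data.frame",
    coverage = "integer"
  )
)

#' Fully labeled synthetic metagenome world
#'
#' Ground-truth fixture: a balanced toy taxonomy, per-species gene
#' sequences derived from genus/phylum ancestors by per-site mutation,
#' reference proteins translated from those genes, and bookkeeping to
#' emit reads and oracle alignments with known labels.
#'
#' @slot taxonomy the toy [Taxonomy].
#' @slot genomes named list (by species taxon id) of named character
#'   vectors of gene DNA sequences.
#' @slot references data.frame (ref_id, protein, taxon_id, class_id,
#'   gene) of reference proteins.
#' @slot params the generator parameters, including the seed.
#' @export
setClass("SyntheticWorld",
  representation(
    taxonomy = "Taxonomy",
    genomes = "list",
    references = "data.frame",
    params = "list"
  )
)
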