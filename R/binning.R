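#' Naive lowest-common-ancestor binning
#'
#' Assigns each read to the LCA of the taxa of all references for which
#' it has a significant alignment. Reads aligning to widely conserved
#' genes therefore land on high-level taxa; reads hitting
#' clade-specific genes land near the leaves, so assignments are spread
#' across all ranks. References mapped to taxa above species rank
#' participate at their own rank (LCA is rank-agnostic).
#'
#' @param aln a significance-filtered alignment data.frame
#'   (see [filterSignificant()]).
#' @param tax a [Taxonomy].
#' @param map a [RefClassMap] resolving `ref_id` to taxon ids.
#' @return A data.frame `(read_id, class_id, algorithm, score_used)`
#'   with one row per read; `class_id` is a taxon id as character or
#'   the [UNASSIGNED] sentinel; `score_used` is the read's best
#'   bitscore. The attribute `"unresolvedRecords"` tallies alignment
#'   rows whose reference could not be resolved to a known taxon.
#' @export
naiveLCA <- function(aln, tax, map) {
  res <- .resolveTaxa(aln, tax, map)
  reads <- unique(aln$read_id)
  out <- data.frame(read_id = reads,
                    class_id = UNASSIGNED,
                    algorithm = "naive-lca",
                    score_used = NA_real_,
                    stringsAsFactors = FALSE)
  byRead <- split(seq_len(nrow(aln)), factor(aln$read_id, levels = reads))
  for (k in seq_along(reads)) {
    i <- byRead[[k]]
    taxa <- res$taxon[i]
    taxa <- taxa[!is.na(taxa)]
    if (length(taxa)) {
      out$class_id[k] <- as.character(lca(tax, taxa))
      out$score_used[k] <- max(aln$bitscore[i])
    }
  }
  attr(out, "unresolvedRecords") <- res$unresolved
  out
}

# resolve every alignment row's ref_id to a taxon id known to `tax`;
# returns list(taxon = integer vector with NA, unresolved = tally)
.resolveTaxa <- function(aln, tax, map) {
  cls <- resolveClass(map, aln$ref_id)
  taxon <- suppressWarnings(as.integer(cls))
  known <- !is.na(taxon) & taxon %in% tax@ids
  taxon[!known] <- NA_integer_
  list(taxon = taxon, unresolved = sum(!known))
}

#' Phase 1 of weighted LCA: reference weights
#'
#' Each reference sequence is weighted by the number of reads that
#' align only to it, or also to other references as long as all of the
#' read's references share one species assignment (the species-rank
#' ancestor of the reference's taxon, or the taxon itself when no
#' species ancestor exists). Reads spanning two or more species
#' contribute to no weight. Afterwards every reference seen in the
#' sample with weight 0 is floored to weight 1, so no read is left with
#' zero total weight in phase 2.
#'
#' @param aln the complete sample's filtered alignment data.frame
#'   (phase 1 is a full pass over the sample).
#' @inheritParams naiveLCA
#' @return A list with `weights` (named integer by `ref_id`) and
#'   `speciesOf` (named integer taxon id by `ref_id`, `NA` when the
#'   reference is unresolvable).
#' @export
computeRefWeights <- function(aln, tax, map) {
  refs <- unique(aln$ref_id)
  refCls <- resolveClass(map, refs)
  refTax <- suppressWarnings(as.integer(refCls))
  refTax[!refTax %in% tax@ids] <- NA_integer_
  speciesOf <- vapply(refTax, function(t) {
    if (is.na(t)) return(NA_integer_)
    sp <- ancestorAtRank(tax, t, "species")
    if (is.na(sp)) t else sp
  }, integer(1))
  names(speciesOf) <- refs
  w <- stats::setNames(integer(length(refs)), refs)
  byRead <- splitByRead(aln)
  for (grp in byRead) {
    sp <- speciesOf[grp$ref_id]
    sp <- sp[!is.na(sp)]
    if (length(sp) && length(unique(sp)) == 1L) {
      tgt <- unique(grp$ref_id[!is.na(speciesOf[grp$ref_id])])
      w[tgt] <- w[tgt] + 1L
    }
  }
  w[w == 0L] <- 1L
  list(weights = w, speciesOf = speciesOf)
}

#' Phase 2 of weighted LCA: coverage-based placement
#'
#' Places each read on the lowest taxonomy node whose subtree contains
#' at least `coverage` (default 0.75) of the total weight of all
#' references the read has significant alignments to. With
#' `coverage > 0.5` the qualifying nodes always form a root-to-node
#' chain, so the deepest qualifying node is unique; this is asserted
#' during traversal. A read whose references are concentrated on one
#' species is placed there; weight spread across a genus places the
#' read on the genus.
#'
#' @inheritParams naiveLCA
#' @param w reference weights from [computeRefWeights()].
#' @param coverage required fraction of total reference weight,
#'   in `(0.5, 1]`.
#' @return As [naiveLCA()], with `algorithm = "weighted-lca"` and
#'   `score_used` the read's total reference weight.
#' @export
weightedLCA <- function(aln, w, tax, map, coverage = 0.75) {
  if (coverage <= 0.5 || coverage > 1) {
    stop("coverage must lie in (0.5, 1]")
  }
  res <- .resolveTaxa(aln, tax, map)
  reads <- unique(aln$read_id)
  out <- data.frame(read_id = reads,
                    class_id = UNASSIGNED,
                    algorithm = "weighted-lca",
                    score_used = NA_real_,
                    stringsAsFactors = FALSE)
  byRead <- split(seq_len(nrow(aln)), factor(aln$read_id, levels = reads))
  for (k in seq_along(reads)) {
    i <- byRead[[k]]
    ok <- !is.na(res$taxon[i])
    if (!any(ok)) next
    refs <- aln$ref_id[i][ok]
    taxa <- res$taxon[i][ok]
    keep <- !duplicated(refs)
    refs <- refs[keep]; taxa <- taxa[keep]
    wr <- w$weights[refs]
    wr[is.na(wr)] <- 1L
    W <- sum(wr)
    # accumulate each reference's weight on every ancestor of its taxon
    cum <- new.env(parent = emptyenv())
    for (j in seq_along(taxa)) {
      for (node in taxPath(tax, taxa[j])) {
        key <- as.character(node)
        cum[[key]] <- (if (is.null(cum[[key]])) 0 else cum[[key]]) + wr[j]
      }
    }
    qual <- as.integer(ls(cum))
    qual <- qual[vapply(as.character(qual), function(k2) cum[[k2]], 0) >=
                   coverage * W]
    d <- taxDepth(tax, qual)
    deepest <- qual[which.max(d)]
    if (!all(qual %in% taxPath(tax, deepest))) {
      stop("internal error: qualifying nodes do not form a chain ",
           "(coverage <= 0.5?)")
    }
    out$class_id[k] <- as.character(deepest)
    out$score_used[k] <- W
  }
  attr(out, "unresolvedRecords") <- res$unresolved
  out
}

#' Promote weakly supported assignments to their parents
#'
#' Low-support pruning: with
#' `threshold = max(minSupport, ceiling(minSupportPercent * assigned))`,
#' any taxon whose on-or-below assignment count is below the threshold
#' has its directly assigned reads re-assigned to its parent,
#' cascading rootward until every populated node meets the threshold.
#' Off by default (`minSupport = 1`, `minSupportPercent = 0`).
#' Re-application is the identity.
#'
#' @param assignments data.frame from [naiveLCA()] / [weightedLCA()].
#' @param tax a [Taxonomy].
#' @param minSupport absolute read-count threshold.
#' @param minSupportPercent threshold as a fraction of assigned reads,
#'   in `[0, 1]`.
#' @return The assignments with `class_id` updated.
#' @export
minSupportFilter <- function(assignments, tax, minSupport = 1L,
                             minSupportPercent = 0) {
  assigned <- assignments$class_id != UNASSIGNED
  nAssigned <- sum(assigned)
  threshold <- max(minSupport, ceiling(minSupportPercent * nAssigned))
  if (threshold <= 1L || !nAssigned) return(assignments)
  node <- as.integer(assignments$class_id[assigned])
  # work over the populated nodes and all their ancestors, deepest
  # first: when a node fails the threshold, every descendant's reads
  # have already cascaded into it
  active <- unique(unlist(lapply(unique(node), function(v) taxPath(tax, v))))
  active <- active[order(taxDepth(tax, active), decreasing = TRUE)]
  readsAt <- lapply(stats::setNames(active, as.character(active)),
                    function(v) which(assigned)[node == v])
  keptBelow <- stats::setNames(integer(length(active)), as.character(active))
  for (v in active) {
    key <- as.character(v)
    support <- length(readsAt[[key]]) + keptBelow[[key]]
    if (support == 0L) next
    if (support < threshold && v != tax@rootId) {
      pkey <- as.character(taxParent(tax, v))
      readsAt[[pkey]] <- c(readsAt[[pkey]], readsAt[[key]])
      readsAt[[key]] <- integer(0)
    } else if (v != tax@rootId) {
      pkey <- as.character(taxParent(tax, v))
      keptBelow[[pkey]] <- keptBelow[[pkey]] + support
    }
  }
  for (key in names(readsAt)) {
    rows <- readsAt[[key]]
    if (length(rows)) assignments$class_id[rows] <- key
  }
  assignments
}

#' Tabulate assignments into per-node direct counts
#'
#' @param assignments data.frame from the LCA binners.
#' @return Named numeric vector, taxon id (character) -> directly
#'   assigned read count; the [UNASSIGNED] bin is included when present.
#' @export
countAssignments <- function(assignments) {
  tab <- table(assignments$class_id)
  stats::setNames(as.numeric(tab), names(tab))
}

# split an integer count among weighted bins by largest remainder;
# ties on the fractional part go to the smaller id
.apportion <- function(count, weights, ids) {
  share <- count * weights / sum(weights)
  base <- floor(share)
  rem <- round(count - sum(base))
  if (rem > 0) {
    ord <- order(-(share - base), ids)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

#' Project across-rank assignments onto a fixed rank
#'
#' Converts read-level binning (spread across all ranks) into a
#' fixed-rank profile. Counts on nodes below the target rank roll up to
#' their ancestor at that rank. Counts on nodes above the rank are
#' pushed down iteratively: each node's directly assigned count is
#' split among those children that carry reads on or below them and
#' that lead to the target rank, proportionally to their on-or-below
#' counts, integerized by largest remainder (fraction ties broken by
#' ascending taxon id). Reads on a node with no descendant at the
#' target rank, or apportioned toward only all-zero subtrees, land in
#' the [UNRESOLVED] bin. The total count is conserved exactly.
#'
#' @param counts named numeric vector, taxon id (character) -> directly
#'   assigned read count (integers); an [UNASSIGNED] entry is passed
#'   through untouched.
#' @param tax a [Taxonomy].
#' @param rank target rank from [taxRanks()] (not `"norank"`).
#' @return Named numeric vector over taxon ids at the target rank,
#'   plus optional [UNRESOLVED] and [UNASSIGNED] bins.
#' @export
projectToRank <- function(counts, tax, rank = "species") {
  if (!rank %in% setdiff(taxRanks(), "norank")) {
    stop("unknown projection rank '", rank, "'")
  }
  out <- numeric(0)
  unresolved <- 0
  unassigned <- 0
  if (UNASSIGNED %in% names(counts)) {
    unassigned <- counts[[UNASSIGNED]]
    counts <- counts[names(counts) != UNASSIGNED]
  }
  if (!length(counts)) return(.projectResult(out, unresolved, unassigned))
  ids <- as.integer(names(counts))
  .taxIndex(tax, ids)
  addTo <- function(vec, key, val) {
    vec[key] <- (if (key %in% names(vec)) vec[[key]] else 0) + val
    vec
  }
  # on-or-below original counts, and reachability of the target rank
  subtree <- stats::setNames(numeric(length(tax@ids)), as.character(tax@ids))
  for (k in seq_along(ids)) {
    for (node in taxPath(tax, ids[k])) {
      subtree[[as.character(node)]] <- subtree[[as.character(node)]] + counts[[k]]
    }
  }
  hasRank <- stats::setNames(logical(length(tax@ids)), as.character(tax@ids))
  for (id in tax@ids[tax@rank == rank]) {
    for (node in taxPath(tax, id)) hasRank[[as.character(node)]] <- TRUE
  }
  pending <- numeric(0)
  for (k in seq_along(ids)) {
    anc <- ancestorAtRank(tax, ids[k], rank)
    if (!is.na(anc)) {
      out <- addTo(out, as.character(anc), counts[[k]])
    } else if (hasRank[[as.character(ids[k])]]) {
      pending <- addTo(pending, as.character(ids[k]), counts[[k]])
    } else {
      unresolved <- unresolved + counts[[k]]
    }
  }
  # push pending counts down, shallowest node first
  while (length(pending)) {
    pids <- as.integer(names(pending))
    v <- pids[which.min(taxDepth(tax, pids))]
    p <- pending[[as.character(v)]]
    pending <- pending[names(pending) != as.character(v)]
    kids <- taxChildren(tax, v)
    elig <- kids[subtree[as.character(kids)] > 0 & hasRank[as.character(kids)]]
    if (!length(elig)) {
      unresolved <- unresolved + p
      next
    }
    shares <- .apportion(p, subtree[as.character(elig)], elig)
    for (j in seq_along(elig)) {
      if (shares[j] == 0) next
      child <- elig[j]
      if (taxRank(tax, child) == rank) {
        out <- addTo(out, as.character(child), shares[j])
      } else {
        pending <- addTo(pending, as.character(child), shares[j])
      }
    }
  }
  .projectResult(out, unresolved, unassigned)
}

.projectResult <- function(out, unresolved, unassigned) {
  if (length(out)) out <- out[order(as.integer(names(out)))]
  if (unresolved > 0) out[UNRESOLVED] <- unresolved
  if (unassigned > 0) out[UNASSIGNED] <- unassigned
  out
}

#' Bin reads to a functional classification
#'
#' Best-hit functional binning: each read is assigned the class of its
#' highest-bitscore alignment whose reference resolves to a class
#' present in the classification tree. Bitscore ties are broken by the
#' earlier record in the read's (stable, descending-score) ordering.
#'
#' @param aln filtered alignment data.frame, ordered within each read
#'   by descending bitscore (as produced by [filterSignificant()]).
#' @param map a [RefClassMap] resolving `ref_id` to functional class
#'   ids.
#' @param ct a [ClassificationTree].
#' @return A data.frame as [naiveLCA()], `algorithm = "best-hit"`.
#' @export
functionalBin <- function(aln, map, ct) {
  cls <- resolveClass(map, aln$ref_id)
  inTree <- !is.na(cls) & (cls %in% names(ct@payload) | cls %in% ct@nodeId)
  reads <- unique(aln$read_id)
  out <- data.frame(read_id = reads, class_id = UNASSIGNED,
                    algorithm = "best-hit", score_used = NA_real_,
                    stringsAsFactors = FALSE)
  byRead <- split(seq_len(nrow(aln)), factor(aln$read_id, levels = reads))
  for (k in seq_along(reads)) {
    i <- byRead[[k]]
    i <- i[inTree[i]]
    if (!length(i)) next
    best <- i[order(-aln$bitscore[i])][1L]
    out$class_id[k] <- cls[best]
    out$score_used[k] <- aln$bitscore[best]
  }
  out
}

#' End-to-end taxonomic binning of one sample
#'
#' Composes the full per-sample pipeline: significance filtering,
#' LCA assignment (naive or weighted), optional min-support promotion,
#' and fixed-rank projection, returning a [SampleProfile] whose counts
#' (including the [UNASSIGNED] bin) sum exactly to `totalReads`.
#'
#' @param aln raw alignment data.frame from [readBlastTab()].
#' @param tax a [Taxonomy].
#' @param map a [RefClassMap].
#' @param sampleName profile label.
#' @param algorithm `"naive"` or `"weighted"`.
#' @param rank projection rank (default `"species"`, the rank used for
#'   species-level sample profiles).
#' @param coverage weighted-LCA coverage fraction.
#' @param minScore,maxExpected,topPercent,minPercentIdentity
#'   significance-filter settings, see [filterSignificant()].
#' @param minSupport,minSupportPercent min-support settings, see
#'   [minSupportFilter()].
#' @param totalReads total reads in the sample; defaults to the number
#'   of distinct read ids in `aln` (i.e. all reads with at least one
#'   alignment).
#' @return A [SampleProfile]; all parameters are recorded in its
#'   `parameters` slot and echoed into file headers by
#'   [writeProfile()].
#' @export
binSample <- function(aln, tax, map, sampleName = "sample",
                      algorithm = c("naive", "weighted"),
                      rank = "species", coverage = 0.75,
                      minScore = 50, maxExpected = 0.01, topPercent = 10,
                      minPercentIdentity = 0,
                      minSupport = 1L, minSupportPercent = 0,
                      totalReads = NULL) {
  algorithm <- match.arg(algorithm)
  if (is.null(totalReads)) totalReads <- length(unique(aln$read_id))
  filt <- filterSignificant(aln, minScore = minScore,
                            maxExpected = maxExpected,
                            topPercent = topPercent,
                            minPercentIdentity = minPercentIdentity)
  assignments <- if (algorithm == "naive") {
    naiveLCA(filt, tax, map)
  } else {
    weightedLCA(filt, computeRefWeights(filt, tax, map), tax, map,
                coverage = coverage)
  }
  assignments <- minSupportFilter(assignments, tax, minSupport,
                                  minSupportPercent)
  counts <- countAssignments(assignments)
  counts <- counts[names(counts) != UNASSIGNED]
  projected <- projectToRank(counts, tax, rank)
  nAssigned <- sum(projected[setdiff(names(projected), UNASSIGNED)])
  projected[UNASSIGNED] <- totalReads - nAssigned
  params <- list(algorithm = algorithm, rank = rank, coverage = coverage,
                 minScore = minScore, maxExpected = maxExpected,
                 topPercent = topPercent,
                 minPercentIdentity = minPercentIdentity,
                 minSupport = minSupport,
                 minSupportPercent = minSupportPercent)
  new("SampleProfile", sampleName = sampleName,
      classificationName = "Taxonomy", counts = projected,
      totalReads = as.integer(totalReads), parameters = params)
}

setMethod("show", "SampleProfile", function(object) {
  cat(sprintf("SampleProfile '%s' (%s): %d classes, %d reads\n",
              object@sampleName, object@classificationName,
              sum(!names(object@counts) %in% c(UNASSIGNED, UNRESOLVED)),
              object@totalReads))
})
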