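#' @importFrom Biostrings DNAStringSet reverseComplement
NULL

.asSeqVector <- function(reads) {
  if (is(reads, "XStringSet")) {
    stats::setNames(as.character(reads), names(reads))
  } else {
    if (length(reads) && is.null(names(reads))) {
      stop("reads must be named by read id")
    }
    reads
  }
}

#' Anchor reads of one class onto their reference proteins
#'
#' First step of gene-centric assembly: among a read's alignments to
#' references that resolve into the target class (for a taxonomic
#' target, on or below the target node), the best-bitscore alignment
#' becomes the read's anchor; bitscore ties are broken by the
#' lexicographically smaller reference id. Reverse-orientation reads
#' are reverse-complemented and their coordinates remapped, so all
#' anchors are forward with respect to the reference frame.
#'
#' @param reads named character vector or `DNAStringSet` of read
#'   sequences.
#' @param aln filtered alignment data.frame (see [filterSignificant()]).
#' @param map a [RefClassMap].
#' @param targetClass class id to assemble (taxon id as character, or a
#'   functional class id).
#' @param tax optional [Taxonomy]; when given and the resolved classes
#'   are taxon ids, a reference qualifies if its taxon lies on or below
#'   `targetClass`.
#' @return data.frame `(read_id, dna, ref_id, ref_start, ref_end,
#'   read_offset, aln_len, frameshift)` where `read_offset` is the
#'   1-based position of the first aligned base on the normalized read
#'   and `frameshift` marks alignments whose nucleotide span is not
#'   three times their amino-acid span. Attribute `"skippedReads"`
#'   tallies reads with no qualifying alignment.
#' @export
anchorReads <- function(reads, aln, map, targetClass, tax = NULL) {
  seqs <- .asSeqVector(reads)
  cls <- resolveClass(map, aln$ref_id)
  qualifies <- !is.na(cls) & if (is.null(tax)) {
    cls == as.character(targetClass)
  } else {
    taxon <- suppressWarnings(as.integer(cls))
    ok <- !is.na(taxon) & taxon %in% tax@ids
    res <- logical(length(cls))
    for (t in unique(taxon[ok])) {
      res[ok & taxon == t] <- isAncestorOrSelf(tax, as.integer(targetClass), t)
    }
    res
  }
  qualifies <- qualifies & aln$read_id %in% names(seqs)
  sub <- aln[qualifies, , drop = FALSE]
  skipped <- length(setdiff(unique(aln$read_id), unique(sub$read_id)))
  if (!nrow(sub)) {
    out <- data.frame(read_id = character(0), dna = character(0),
                      ref_id = character(0), ref_start = integer(0),
                      ref_end = integer(0), read_offset = integer(0),
                      aln_len = integer(0), frameshift = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "skippedReads") <- skipped
    return(out)
  }
  sub <- sub[order(sub$read_id, -sub$bitscore, sub$ref_id), , drop = FALSE]
  sub <- sub[!duplicated(sub$read_id), , drop = FALSE]
  dna <- seqs[sub$read_id]
  len <- nchar(dna)
  rs <- sub$read_start
  re <- sub$read_end
  rev <- sub$reverse
  if (any(rev)) {
    dna[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(dna[rev])))
    newStart <- len[rev] - re[rev] + 1L
    re[rev] <- len[rev] - rs[rev] + 1L
    rs[rev] <- newStart
  }
  out <- data.frame(
    read_id = sub$read_id, dna = unname(dna), ref_id = sub$ref_id,
    ref_start = sub$ref_start, ref_end = sub$ref_end,
    read_offset = rs, aln_len = re - rs + 1L,
    frameshift = (re - rs + 1L) != 3L * (sub$ref_end - sub$ref_start + 1L),
    stringsAsFactors = FALSE)
  attr(out, "skippedReads") <- skipped
  out
}

.baseMatches <- function(a, b) {
  sum(utf8ToInt(a) == utf8ToInt(b))
}

#' Infer verified DNA overlaps between anchored reads
#'
#' Two reads anchored to the same reference protein with overlapping
#' amino-acid intervals imply a relative nucleotide placement: placing
#' read start `r` at gene position `3 * ref_start - 2 - (read_offset -
#' 1)`, the shift between two reads follows from their anchors. The
#' implied overlap is then verified by direct base comparison over the
#' full overlapping span of the two reads; an edge is added only when
#' the span reaches `minOverlap` nucleotides and the match fraction
#' reaches `minIdentity`. Frameshift-anchored reads are excluded, since
#' an internal indel would make the implied shift unreliable.
#'
#' @param anchored data.frame from [anchorReads()].
#' @param minOverlap minimum verified overlap in nt (default 20).
#' @param minIdentity minimum overlap identity fraction (default 0.98).
#' @return An [OverlapGraph].
#' @export
inferOverlaps <- function(anchored, minOverlap = 20L, minIdentity = 0.98) {
  anchored <- anchored[!anchored$frameshift, , drop = FALSE]
  edges <- list()
  for (ref in unique(anchored$ref_id)) {
    grp <- anchored[anchored$ref_id == ref, , drop = FALSE]
    grp <- grp[order(grp$read_id), , drop = FALSE]
    if (nrow(grp) < 2L) next
    gpos <- 3L * grp$ref_start - 2L - (grp$read_offset - 1L)
    glen <- nchar(grp$dna)
    for (i in seq_len(nrow(grp) - 1L)) {
      for (j in seq(i + 1L, nrow(grp))) {
        if (grp$ref_start[j] > grp$ref_end[i] ||
            grp$ref_start[i] > grp$ref_end[j]) next
        ovStart <- max(gpos[i], gpos[j])
        ovEnd <- min(gpos[i] + glen[i] - 1L, gpos[j] + glen[j] - 1L)
        span <- ovEnd - ovStart + 1L
        if (span < minOverlap) next
        su <- substr(grp$dna[i], ovStart - gpos[i] + 1L, ovEnd - gpos[i] + 1L)
        sv <- substr(grp$dna[j], ovStart - gpos[j] + 1L, ovEnd - gpos[j] + 1L)
        ident <- .baseMatches(su, sv) / span
        if (ident < minIdentity) next
        edges[[length(edges) + 1L]] <- data.frame(
          u = grp$read_id[i], v = grp$read_id[j],
          shift = gpos[j] - gpos[i], overlap_len = span,
          identity = ident, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(u = character(0), v = character(0), shift = integer(0),
               overlap_len = integer(0), identity = numeric(0),
               stringsAsFactors = FALSE)
  }
  new("OverlapGraph", reads = anchored, edges = edges,
      minOverlap = as.integer(minOverlap), minIdentity = minIdentity)
}

# union-find over read placements with relative offsets
.ufFind <- function(uf, x) {
  off <- 0L
  while (uf$parent[[x]] != x) {
    off <- off + uf$offset[[x]]
    x <- uf$parent[[x]]
  }
  list(root = x, offset = off)
}

#' Extract consensus contigs from an overlap graph
#'
#' Greedy chain merging: edges are processed in descending
#' `(overlap_len, identity)` order (ties by vertex ids) and an edge
#' merges its endpoints' chains when the implied placements are
#' mutually consistent -- no read is placed twice and shifts must agree
#' exactly. The consensus is a per-column majority vote over the member
#' reads, ties resolved by the base of the member with the smallest
#' read id. Singleton reads are never emitted; contigs shorter than
#' `minLength` are discarded. Contigs are ordered by decreasing length
#' then by smallest member read id and named `contig_1, contig_2, ...`,
#' so identical inputs yield byte-identical output.
#'
#' @param g an [OverlapGraph].
#' @param minLength minimum consensus length in nt (default 200).
#' @return List of [Contig] objects.
#' @export
extractContigs <- function(g, minLength = 200L) {
  e <- g@edges
  if (!nrow(e)) return(list())
  e <- e[order(-e$overlap_len, -e$identity, e$u, e$v), , drop = FALSE]
  ids <- g@reads$read_id
  uf <- list(parent = stats::setNames(ids, ids),
             offset = stats::setNames(numeric(length(ids)), ids))
  for (i in seq_len(nrow(e))) {
    fu <- .ufFind(uf, e$u[i])
    fv <- .ufFind(uf, e$v[i])
    if (fu$root == fv$root) {
      next  # consistent placements already enforced; conflicting edge skipped
    }
    # want pos(v) - pos(u) == shift
    uf$parent[[fv$root]] <- fu$root
    uf$offset[[fv$root]] <- fu$offset + e$shift[i] - fv$offset
  }
  roots <- vapply(ids, function(x) .ufFind(uf, x)$root, "")
  offsets <- vapply(ids, function(x) as.numeric(.ufFind(uf, x)$offset),
                    numeric(1))
  comps <- split(seq_along(ids), roots)
  comps <- comps[lengths(comps) >= 2L]
  contigs <- list()
  for (comp in comps) {
    readIds <- ids[comp]
    ord <- order(readIds)
    readIds <- readIds[ord]
    seqs <- g@reads$dna[comp][ord]
    starts <- offsets[comp][ord]
    starts <- starts - min(starts) + 1L
    width <- max(starts + nchar(seqs) - 1L)
    tallyBases <- c("A", "C", "G", "T", "N")
    tally <- matrix(0L, length(tallyBases), width,
                    dimnames = list(tallyBases, NULL))
    charRows <- lapply(seqs, function(s) strsplit(s, "")[[1L]])
    for (r in seq_along(seqs)) {
      pos <- starts[r]:(starts[r] + nchar(seqs[r]) - 1L)
      b <- charRows[[r]]
      b[!b %in% tallyBases] <- "N"
      for (base in unique(b)) {
        tally[base, pos[b == base]] <- tally[base, pos[b == base]] + 1L
      }
    }
    consensus <- character(width)
    coverage <- colSums(tally)
    for (col in seq_len(width)) {
      cnt <- tally[, col]
      best <- tallyBases[cnt == max(cnt) & cnt > 0L]
      if (length(best) == 1L) {
        consensus[col] <- best
      } else {
        # smallest-read-id member covering this column whose base ties
        for (r in seq_along(seqs)) {
          p <- col - starts[r] + 1L
          if (p >= 1L && p <= nchar(seqs[r]) && charRows[[r]][p] %in% best) {
            consensus[col] <- charRows[[r]][p]
            break
          }
        }
      }
    }
    if (width < minLength) next
    contigs[[length(contigs) + 1L]] <- list(
      consensus = paste(consensus, collapse = ""),
      members = data.frame(read_id = readIds, start = as.integer(starts),
                           stringsAsFactors = FALSE),
      coverage = as.integer(coverage))
  }
  if (!length(contigs)) return(list())
  ord <- order(-vapply(contigs, function(x) nchar(x$consensus), 0L),
               vapply(contigs, function(x) min(x$members$read_id), ""))
  contigs <- contigs[ord]
  lapply(seq_along(contigs), function(i) {
    new("Contig", contigId = paste0("contig_", i),
        consensus = contigs[[i]]$consensus,
        members = contigs[[i]]$members,
        coverage = contigs[[i]]$coverage)
  })
}

#' Gene-centric assembly of one class
#'
#' End-to-end composition: anchor the class's reads on their reference
#' proteins, infer and verify DNA overlaps, and extract consensus
#' contigs. Deterministic for fixed inputs and parameters.
#'
#' @inheritParams anchorReads
#' @inheritParams inferOverlaps
#' @inheritParams extractContigs
#' @return List of [Contig] objects.
#' @export
assembleClass <- function(reads, aln, map, targetClass, tax = NULL,
                          minOverlap = 20L, minIdentity = 0.98,
                          minLength = 200L) {
  anchored <- anchorReads(reads, aln, map, targetClass, tax = tax)
  g <- inferOverlaps(anchored, minOverlap = minOverlap,
                     minIdentity = minIdentity)
  extractContigs(g, minLength = minLength)
}

#' Re-verify that contig members match their consensus
#'
#' Post-hoc soundness check: the fraction of matching bases of each
#' member read over its recorded placement on the consensus.
#'
#' @param contig a [Contig].
#' @param reads named character vector of the (orientation-normalized)
#'   member read sequences, e.g. column `dna` of [anchorReads()].
#' @return Named numeric vector of per-member identities.
#' @export
contigMemberIdentity <- function(contig, reads) {
  vapply(seq_len(nrow(contig@members)), function(i) {
    rid <- contig@members$read_id[i]
    s <- reads[[rid]]
    st <- contig@members$start[i]
    ref <- substr(contig@consensus, st, st + nchar(s) - 1L)
    .baseMatches(ref, s) / nchar(s)
  }, numeric(1)) |> stats::setNames(contig@members$read_id)
}

#' Write contigs to FASTA with coverage annotations
#'
#' Headers carry length, member count and mean coverage, e.g.
#' `>contig_1 len=600 reads=11 cov=1.83`.
#'
#' @param contigs list of [Contig] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeContigsFasta <- function(contigs, file) {
  lines <- unlist(lapply(contigs, function(ct) {
    c(sprintf(">%s len=%d reads=%d cov=%.2f", ct@contigId,
              nchar(ct@consensus), nrow(ct@members), mean(ct@coverage)),
      ct@consensus)
  }))
  writeLines(if (is.null(lines)) character(0) else lines, file)
  invisible(file)
}

setMethod("show", "OverlapGraph", function(object) {
  cat(sprintf("OverlapGraph: %d reads, %d verified overlaps (>=%d nt, >=%.2f id)\n",
              nrow(object@reads), nrow(object@edges), object@minOverlap,
              object@minIdentity))
})

setMethod("show", "Contig", function(object) {
  cat(sprintf("Contig %s: %d nt, %d reads, mean coverage %.2f\n",
              object@contigId, nchar(object@consensus),
              nrow(object@members), mean(object@coverage)))
})
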