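.GO_DOMAINS <- c(
  "biological process" = "GO:0008150",
  "cellular component" = "GO:0005575",
  "molecular function" = "GO:0003674"
)

#' Build the InterPro-to-GO-slim classification tree
#'
#' Constructs the four-tier functional classification used to bin
#' reads by InterPro family under a GO-slim scaffold:
#'
#' * tier 1: the three Gene Ontology domain nodes, labeled exactly
#'   `"GO:0008150 biological process"`, `"GO:0005575 cellular
#'   component"` and `"GO:0003674 molecular function"`, plus an
#'   `"Unclassified"` catch-all node;
#' * tier 2: one node per GO-slim term, attached under its domain node;
#' * tier 3: InterPro family nodes. For each family and each GO domain,
#'   the family's GO annotations are reduced to the slim terms they map
#'   to (via `goAncestry`). Exactly one slim term in a domain places
#'   the family under that term; two or more place it under a
#'   lazily-created `"Other"` child of the domain node. A family with
#'   no usable GO annotation goes under `"Unclassified"`.
#'
#' By construction each family occurs at most three times, at most once
#' below each domain node. A GO annotation with no slim ancestor in any
#' domain is treated as absent for that term and tallied in the
#' `"droppedTerms"` attribute, not an error. Families are processed in
#' lexicographic accession order, so rebuilding from the same inputs is
#' bit-identical.
#'
#' @param familyToGo named list: InterPro accession -> character vector
#'   of annotated GO term ids (possibly empty).
#' @param goslimTerms data.frame `(go_id, label, domain)` of slim terms,
#'   `domain` one of `names(.GO_DOMAINS)` ("biological process",
#'   "cellular component", "molecular function").
#' @param goAncestry named list: GO term id -> character vector of its
#'   GO-slim ancestor term ids (a slim term should list itself).
#' @param familyLabels named character: accession -> family label;
#'   families absent from `familyToGo` are treated as unannotated.
#' @return A [ClassificationTree] named `"InterPro2GO"` whose payload
#'   maps each accession to its 1-3 node placements.
#' @export
buildInterpro2GO <- function(familyToGo, goslimTerms, goAncestry,
                             familyLabels) {
  if (!all(goslimTerms$domain %in% names(.GO_DOMAINS))) {
    stop("slim term domain outside the three GO domains: ",
         setdiff(goslimTerms$domain, names(.GO_DOMAINS))[1L])
  }
  nodeId <- character(0); parentId <- character(0); label <- character(0)
  addNode <- function(id, parent, lab) {
    nodeId[[length(nodeId) + 1L]] <<- id
    parentId[[length(parentId) + 1L]] <<- parent
    label[[length(label) + 1L]] <<- lab
  }
  for (d in names(.GO_DOMAINS)) {
    addNode(.GO_DOMAINS[[d]], NA_character_, paste(.GO_DOMAINS[[d]], d))
  }
  addNode("Unclassified", NA_character_, "Unclassified")
  slimDomain <- stats::setNames(goslimTerms$domain, goslimTerms$go_id)
  for (i in order(goslimTerms$go_id)) {
    addNode(goslimTerms$go_id[i], .GO_DOMAINS[[goslimTerms$domain[i]]],
            paste(goslimTerms$go_id[i], goslimTerms$label[i]))
  }
  otherMade <- character(0)
  payload <- list()
  dropped <- 0L
  for (acc in sort(names(familyLabels))) {
    terms <- familyToGo[[acc]]
    slims <- character(0)
    for (g in terms) {
      anc <- goAncestry[[g]]
      anc <- anc[anc %in% goslimTerms$go_id]
      if (!length(anc)) dropped <- dropped + 1L
      slims <- c(slims, anc)
    }
    slims <- unique(slims)
    placements <- character(0)
    if (!length(slims)) {
      id <- paste0(acc, "@Unclassified")
      addNode(id, "Unclassified", familyLabels[[acc]])
      placements <- id
    } else {
      for (d in names(.GO_DOMAINS)) {
        dslims <- slims[slimDomain[slims] == d]
        if (!length(dslims)) next
        dom <- .GO_DOMAINS[[d]]
        parent <- if (length(dslims) == 1L) {
          dslims
        } else {
          oid <- paste0(dom, ":Other")
          if (!oid %in% otherMade) {
            addNode(oid, dom, "Other")
            otherMade <- c(otherMade, oid)
          }
          oid
        }
        id <- paste0(acc, "@", dom)
        addNode(id, parent, familyLabels[[acc]])
        placements <- c(placements, id)
      }
    }
    payload[[acc]] <- placements
  }
  ct <- new("ClassificationTree", name = "InterPro2GO",
            nodeId = nodeId, parentId = parentId, label = label,
            roots = c(unname(.GO_DOMAINS), "Unclassified"),
            payload = payload)
  attr(ct, "droppedTerms") <- dropped
  validObject(ct)
  ct
}

#' Load a generic functional hierarchy from a 3-column TSV
#'
#' Carrier for subsystem/functional-role or orthologous-group style
#' hierarchies: rows are `class_id<TAB>parent_id<TAB>label` with the
#' literal parent `ROOT` marking tier-1 nodes. Parents may appear after
#' their children (resolved in a second pass). Every node id is
#' binnable, inner nodes included.
#'
#' @param file path to the TSV (`#` comment lines skipped).
#' @param name classification name recorded in the tree.
#' @return A [ClassificationTree]; empty input yields a valid empty
#'   tree against which binning always returns [UNASSIGNED].
#' @export
loadHierarchy <- function(file, name = "Hierarchy") {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(new("ClassificationTree", name = name,
               nodeId = character(0), parentId = character(0),
               label = character(0), roots = character(0),
               payload = list()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("hierarchy row with fewer than 3 fields at line ",
         which(lengths(parts) < 3L)[1L])
  }
  id <- vapply(parts, `[`, "", 1L)
  parent <- vapply(parts, `[`, "", 2L)
  lab <- vapply(parts, `[`, "", 3L)
  if (anyDuplicated(id)) {
    stop("duplicate class_id '", id[anyDuplicated(id)], "'")
  }
  parent[parent == "ROOT"] <- NA_character_
  missing <- !is.na(parent) & !parent %in% id
  if (any(missing)) {
    stop("orphan parent id '", parent[missing][1L], "'")
  }
  new("ClassificationTree", name = name, nodeId = id, parentId = parent,
      label = lab, roots = id[is.na(parent)],
      payload = stats::setNames(as.list(id), id))
}

#' Roll read counts up a classification tree
#'
#' Computes, for every node, the number of reads assigned directly to
#' it and the summarized count (assigned plus the sum of the children's
#' summarized counts) -- the quantity displayed as "reads assigned to
#' the node, or below it". When a payload id (e.g. an InterPro family)
#' is placed at several tree positions, each placement receives the
#' full per-read count, so a read is visible under every GO domain its
#' family maps to; sums over tier-1 nodes may then exceed the number of
#' classified reads. This multi-counting is recorded in output headers
#' by [writeProfile()].
#'
#' @param ct a [ClassificationTree].
#' @param assignments data.frame from [functionalBin()]; `class_id`
#'   values are payload ids or [UNASSIGNED].
#' @return A data.frame `(class_id, label, assigned, summarized)` in
#'   the tree's node order, with attribute `"unknownClasses"` tallying
#'   assignments to ids absent from the tree.
#' @export
rollupCounts <- function(ct, assignments) {
  assigned <- stats::setNames(numeric(length(ct@nodeId)), ct@nodeId)
  unknown <- 0L
  cls <- assignments$class_id
  cls <- cls[cls != UNASSIGNED]
  for (cid in cls) {
    nodes <- ct@payload[[cid]]
    if (is.null(nodes) && cid %in% ct@nodeId) nodes <- cid
    if (is.null(nodes)) {
      unknown <- unknown + 1L
      next
    }
    assigned[nodes] <- assigned[nodes] + 1
  }
  summarized <- assigned
  # children sum bottom-up: process nodes deepest-first
  depth <- .ctDepth(ct)
  for (i in order(depth, decreasing = TRUE)) {
    p <- ct@parentId[i]
    if (!is.na(p)) summarized[[p]] <- summarized[[p]] + summarized[[i]]
  }
  out <- data.frame(class_id = ct@nodeId, label = ct@label,
                    assigned = unname(assigned),
                    summarized = unname(summarized),
                    stringsAsFactors = FALSE)
  attr(out, "unknownClasses") <- unknown
  out
}

.ctDepth <- function(ct) {
  depth <- rep(NA_integer_, length(ct@nodeId))
  names(depth) <- ct@nodeId
  depth[is.na(ct@parentId)] <- 0L
  while (anyNA(depth)) {
    todo <- which(is.na(depth))
    d <- depth[ct@parentId[todo]]
    depth[todo[!is.na(d)]] <- d[!is.na(d)] + 1L
    if (all(is.na(d))) stop("cycle in classification tree")
  }
  unname(depth)
}

#' Number of tree placements of each payload id
#'
#' @param ct a [ClassificationTree].
#' @return Named integer: payload id -> number of nodes carrying it.
#' @export
payloadOccurrences <- function(ct) {
  vapply(ct@payload, length, integer(1))
}

#' Read the EBI InterPro-to-GO mapping line dialect
#'
#' Lines of the form
#' `InterPro:IPR000001 Kringle > GO:Blood coagulation ; GO:0007596`;
#' comment lines start with `!`. Returns the accession -> GO terms
#' mapping plus family labels.
#'
#' @param file path to an `interpro2go`-style file.
#' @return List with `familyToGo` (named list) and `familyLabels`
#'   (named character).
#' @export
readInterpro2GoMap <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  familyToGo <- list()
  familyLabels <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec(
      "^InterPro:(\\S+)\\s+(.*?)\\s*>\\s*GO:.*;\\s*(GO:\\d+)\\s*$", ln))[[1L]]
    if (length(m) != 4L) stop("unparseable interpro2go line: ", ln)
    acc <- m[2L]
    familyLabels[acc] <- m[3L]
    familyToGo[[acc]] <- c(familyToGo[[acc]], m[4L])
  }
  list(familyToGo = familyToGo, familyLabels = familyLabels)
}

#' Read a 3-column GO-slim term table
#'
#' Rows are `go_id<TAB>label<TAB>domain`.
#'
#' @param file path to the TSV.
#' @return data.frame `(go_id, label, domain)`.
#' @export
readGoslimTerms <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           comment.char = "#", colClasses = "character",
                           quote = "")
  stats::setNames(tab[, 1:3], c("go_id", "label", "domain"))
}

#' Read a 2-column GO -> GO-slim ancestry table
#'
#' Rows are `go_id<TAB>slim_ancestor_id`; a term may have several slim
#' ancestors (one row each).
#'
#' @param file path to the TSV.
#' @return Named list: GO id -> character vector of slim ancestors.
#' @export
readGoAncestry <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           comment.char = "#", colClasses = "character",
                           quote = "")
  split(tab[[2L]], tab[[1L]])
}

setMethod("show", "ClassificationTree", function(object) {
  cat(sprintf("ClassificationTree '%s': %d nodes, %d roots, %d payload ids\n",
              object@name, length(object@nodeId), length(object@roots),
              length(object@payload)))
})
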