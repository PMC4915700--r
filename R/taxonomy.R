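#' Construct a Taxonomy from parallel node vectors
#'
#' Low-level constructor used by [loadTaxonomy()] and the synthetic
#' world generator. The root is the unique node with `parent == id`.
#'
#' @param ids integer taxon ids.
#' @param parent integer parent ids (root points to itself).
#' @param rank character ranks; strings outside [taxRanks()] are mapped
#'   to `"norank"`.
#' @param name character node names; defaults to the id as text.
#' @return A validated [Taxonomy] object.
#' @export
#' @examples
#' tax <- newTaxonomy(ids = c(1L, 2L, 3L), parent = c(1L, 1L, 2L),
#'                    rank = c("root", "genus", "species"))
#' taxDepth(tax, 3L)
newTaxonomy <- function(ids, parent, rank, name = as.character(ids)) {
  ids <- as.integer(ids)
  parent <- as.integer(parent)
  if (anyDuplicated(ids)) {
    stop("duplicated taxon_id: ", ids[anyDuplicated(ids)])
  }
  if (any(ids <= 0L) || any(parent <= 0L)) stop("taxon ids must be positive")
  rank <- as.character(rank)
  rank[!rank %in% taxRanks()] <- "norank"
  pidx <- match(parent, ids)
  if (anyNA(pidx)) stop("unknown parent id: ", parent[is.na(pidx)][1L])
  rooti <- which(parent == ids)
  if (length(rooti) != 1L) {
    stop("expected exactly one root (parent_id == taxon_id), found ",
         length(rooti))
  }
  n <- length(ids)
  depth <- rep(NA_integer_, n)
  depth[rooti] <- 0L
  frontier <- rooti
  while (length(frontier)) {
    nxt <- which(pidx %in% frontier & is.na(depth))
    depth[nxt] <- depth[pidx[nxt]] + 1L
    frontier <- nxt
  }
  if (anyNA(depth)) {
    stop("cycle detected involving taxon ", ids[which(is.na(depth))[1L]])
  }
  kids <- split(ids[-rooti], factor(parent[-rooti], levels = ids))
  kids <- lapply(kids, function(x) sort(as.integer(x)))
  new("Taxonomy", ids = ids, parent = parent, rank = rank,
      name = as.character(name), children = kids,
      depth = depth, rootId = ids[rooti])
}

.taxIndex <- function(tax, id) {
  i <- match(as.integer(id), tax@ids)
  if (anyNA(i)) stop("unknown taxon id: ", id[is.na(i)][1L])
  i
}

#' @describeIn newTaxonomy Number of nodes in the taxonomy.
#' @param tax a [Taxonomy].
#' @export
taxSize <- function(tax) length(tax@ids)

#' Taxonomy node accessors
#'
#' Look up depth, rank, name, parent or children of taxon nodes.
#' All are total over the taxonomy's id set and error on unknown ids.
#'
#' @param tax a [Taxonomy].
#' @param id integer taxon id(s).
#' @return `taxDepth`, `taxParent`: integer; `taxRank`, `taxName`:
#'   character; `taxChildren`: integer vector of child ids, sorted
#'   ascending.
#' @export
taxDepth <- function(tax, id) tax@depth[.taxIndex(tax, id)]

#' @rdname taxDepth
#' @export
taxRank <- function(tax, id) tax@rank[.taxIndex(tax, id)]

#' @rdname taxDepth
#' @export
taxName <- function(tax, id) tax@name[.taxIndex(tax, id)]

#' @rdname taxDepth
#' @export
taxParent <- function(tax, id) tax@parent[.taxIndex(tax, id)]

#' @rdname taxDepth
#' @export
taxChildren <- function(tax, id) {
  .taxIndex(tax, id)  # existence check
  kids <- tax@children[[as.character(as.integer(id))]]
  if (is.null(kids)) integer(0) else kids
}

#' Root-to-node path of taxon ids
#'
#' @param tax a [Taxonomy].
#' @param id a single taxon id.
#' @return Integer vector of taxon ids from the root down to `id`
#'   inclusive.
#' @export
taxPath <- function(tax, id) {
  i <- .taxIndex(tax, id)
  path <- integer(tax@depth[i] + 1L)
  k <- length(path)
  repeat {
    path[k] <- tax@ids[i]
    if (tax@ids[i] == tax@rootId) break
    k <- k - 1L
    i <- match(tax@parent[i], tax@ids)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that is ancestral-or-equal to every id in
#' the set: the node a read is assigned to under naive LCA binning when
#' the ids are the taxa of its significant alignments.
#'
#' @param tax a [Taxonomy].
#' @param ids non-empty vector of taxon ids (duplicates allowed).
#' @return A single taxon id. `lca(tax, x)` is `x` for a singleton.
#' @export
#' @examples
#' tax <- newTaxonomy(c(1L, 10L, 11L, 12L), c(1L, 1L, 10L, 10L),
#'                    c("root", "genus", "species", "species"))
#' lca(tax, c(11L, 12L))  # 10
lca <- function(tax, ids) {
  ids <- unique(as.integer(ids))
  if (!length(ids)) stop("lca of an empty id set is undefined")
  path <- taxPath(tax, ids[1L])
  for (id in ids[-1L]) {
    other <- taxPath(tax, id)
    m <- min(length(path), length(other))
    eq <- path[seq_len(m)] == other[seq_len(m)]
    k <- if (all(eq)) m else which(!eq)[1L] - 1L
    path <- path[seq_len(k)]
  }
  path[length(path)]
}

#' Nearest ancestor-or-self at a given rank
#'
#' Walks rootward from `id` (starting at the node itself) and returns
#' the first node whose rank equals `rank`, or `NA` when no node at
#' that rank lies on the path. `norank` nodes are transparent.
#'
#' @param tax a [Taxonomy].
#' @param id a single taxon id.
#' @param rank a rank name from [taxRanks()].
#' @return A taxon id or `NA_integer_`.
#' @export
ancestorAtRank <- function(tax, id, rank) {
  if (!rank %in% taxRanks()) stop("unknown rank '", rank, "'")
  i <- .taxIndex(tax, id)
  repeat {
    if (tax@rank[i] == rank) return(tax@ids[i])
    if (tax@ids[i] == tax@rootId) return(NA_integer_)
    i <- match(tax@parent[i], tax@ids)
  }
}

#' Test ancestry between two taxa
#'
#' @param tax a [Taxonomy].
#' @param anc,id single taxon ids.
#' @return `TRUE` iff `anc` is an ancestor of `id` or equal to it.
#' @export
isAncestorOrSelf <- function(tax, anc, id) {
  anc <- as.integer(anc)
  as.integer(anc) %in% taxPath(tax, id)
}

#' Load a taxonomy from NCBI-style dump files or a plain TSV
#'
#' Two dialects are auto-detected by delimiter:
#' * the NCBI taxdump dialect: `nodes.dmp` rows
#'   `taxid\t|\tparent\t|\trank\t|\t...` plus a `names.dmp` carrying
#'   `taxid\t|\tname\t|\t...\t|\tname class\t|`; the `"scientific name"`
#'   class is preferred when several names exist;
#' * a plain 4-column TSV `id<TAB>parent<TAB>rank<TAB>name` (then
#'   `namesFile` is not needed).
#'
#' Unknown rank strings map to `"norank"`. Structural problems (cycles,
#' unknown parents, duplicate ids) are errors naming the offending id.
#'
#' @param nodesFile path to `nodes.dmp` or the 4-column TSV.
#' @param namesFile path to `names.dmp`; optional for the TSV dialect.
#' @return A [Taxonomy].
#' @export
loadTaxonomy <- function(nodesFile, namesFile = NULL) {
  lines <- readLines(nodesFile, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty taxonomy source: ", nodesFile)
  if (grepl("\t|\t", lines[1L], fixed = TRUE) || grepl("\t\\|$", lines[1L])) {
    parts <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
    ids <- as.integer(vapply(parts, `[`, "", 1L))
    parent <- as.integer(vapply(parts, `[`, "", 2L))
    rank <- trimws(vapply(parts, `[`, "", 3L))
    name <- as.character(ids)
    if (!is.null(namesFile)) {
      nl <- readLines(namesFile, warn = FALSE)
      nl <- nl[nzchar(trimws(nl))]
      np <- strsplit(sub("\t\\|$", "", nl), "\t\\|\t")
      nid <- as.integer(vapply(np, `[`, "", 1L))
      nname <- trimws(vapply(np, `[`, "", 2L))
      nclass <- trimws(vapply(np, function(p) if (length(p) >= 4) p[4L] else "", ""))
      keep <- order(nid, nclass != "scientific name")
      nid <- nid[keep]; nname <- nname[keep]
      first <- !duplicated(nid)
      hit <- match(ids, nid[first])
      name <- ifelse(is.na(hit), name, nname[first][hit])
    }
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L)) {
      stop("taxonomy TSV row with fewer than 3 fields at line ",
           which(lengths(parts) < 3L)[1L])
    }
    ids <- as.integer(vapply(parts, `[`, "", 1L))
    parent <- as.integer(vapply(parts, `[`, "", 2L))
    rank <- trimws(vapply(parts, `[`, "", 3L))
    name <- vapply(parts, function(p) if (length(p) >= 4L) p[4L] else "", "")
    name[!nzchar(name)] <- as.character(ids)[!nzchar(name)]
  }
  if (anyNA(ids) || anyNA(parent)) {
    stop("non-numeric taxon or parent id at line ",
         which(is.na(ids) | is.na(parent))[1L])
  }
  newTaxonomy(ids, parent, rank, name)
}

#' Write a taxonomy as a 4-column TSV (debug dump)
#'
#' @param tax a [Taxonomy].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTaxonomy <- function(tax, file) {
  utils::write.table(
    data.frame(id = tax@ids, parent = tax@parent, rank = tax@rank,
               name = tax@name),
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

setMethod("show", "Taxonomy", function(object) {
  cat(sprintf("Taxonomy with %d nodes (root id %d, max depth %d)\n",
              length(object@ids), object@rootId, max(object@depth)))
  tab <- table(factor(object@rank, levels = taxRanks()))
  tab <- tab[tab > 0]
  cat("  ranks:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
})
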