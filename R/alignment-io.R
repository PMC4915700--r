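#' @importFrom data.table fread data.table setorder as.data.table := .N .SD
NULL

.ALN_COLS <- c("read_id", "ref_id", "pident", "length", "mismatch",
               "gapopen", "read_start", "read_end", "ref_start", "ref_end",
               "evalue", "bitscore")

#' Read a 12-column tabular alignment file (BLAST outfmt 6 / "m8")
#'
#' Parses DNA-to-protein alignment rows in the standard tab-separated
#' order (qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore). Query coordinates are 1-based
#' inclusive nucleotide positions on the read; `qstart > qend` encodes
#' a reverse-strand (negative frame) alignment and is normalized to
#' `read_start < read_end` with `reverse = TRUE`, so downstream code
#' always sees forward intervals. Rows are expected read-contiguous:
#' all alignments of one read occur in one block.
#'
#' @param file path to a (optionally gzip-compressed) alignment TSV.
#' @param checkContiguity error if a read id block reappears after it
#'   has been closed (default `TRUE`).
#' @return A `data.frame` with columns
#'   `read_id, ref_id, pident, length, mismatch, gapopen, read_start,
#'   read_end, ref_start, ref_end, evalue, bitscore, reverse`.
#' @export
readBlastTab <- function(file, checkContiguity = TRUE) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  parseBlastTab(lines, checkContiguity = checkContiguity)
}

#' @rdname readBlastTab
#' @param lines character vector of raw alignment rows.
#' @export
parseBlastTab <- function(lines, checkContiguity = TRUE) {
  lines <- lines[nzchar(lines)]
  empty <- data.frame(read_id = character(), ref_id = character(),
                      pident = numeric(), length = integer(),
                      mismatch = integer(), gapopen = integer(),
                      read_start = integer(), read_end = integer(),
                      ref_start = integer(), ref_end = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      reverse = logical(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 12L)
  if (length(short)) {
    stop("alignment row with fewer than 12 fields at line ", short[1L])
  }
  field <- function(k) vapply(parts, `[`, "", k)
  num <- function(k, what) {
    x <- suppressWarnings(as.numeric(field(k)))
    if (anyNA(x)) stop("non-numeric ", what, " at line ", which(is.na(x))[1L])
    x
  }
  aln <- data.frame(
    read_id = field(1L), ref_id = field(2L),
    pident = num(3L, "percent identity"),
    length = as.integer(num(4L, "alignment length")),
    mismatch = as.integer(num(5L, "mismatch count")),
    gapopen = as.integer(num(6L, "gap-open count")),
    read_start = as.integer(num(7L, "query start")),
    read_end = as.integer(num(8L, "query end")),
    ref_start = as.integer(num(9L, "subject start")),
    ref_end = as.integer(num(10L, "subject end")),
    evalue = num(11L, "e-value"),
    bitscore = num(12L, "bit score"),
    stringsAsFactors = FALSE)
  if (any(aln$read_start <= 0L | aln$read_end <= 0L |
          aln$ref_start <= 0L | aln$ref_end <= 0L)) {
    stop("non-positive alignment coordinate at line ",
         which(aln$read_start <= 0L | aln$read_end <= 0L |
               aln$ref_start <= 0L | aln$ref_end <= 0L)[1L])
  }
  if (any(aln$bitscore < 0) || any(aln$evalue < 0)) {
    stop("negative score at line ",
         which(aln$bitscore < 0 | aln$evalue < 0)[1L])
  }
  aln$reverse <- aln$read_start > aln$read_end
  if (any(aln$reverse)) {
    s <- aln$read_start[aln$reverse]
    aln$read_start[aln$reverse] <- aln$read_end[aln$reverse]
    aln$read_end[aln$reverse] <- s
  }
  if (checkContiguity) {
    blocks <- rle(aln$read_id)$values
    if (anyDuplicated(blocks)) {
      stop("read id '", blocks[anyDuplicated(blocks)][1L],
           "' reappears after its block closed (input not read-contiguous)")
    }
  }
  aln
}

#' Serialize alignment rows back to the tabular dialect
#'
#' Inverse of [parseBlastTab()]: reverse-orientation rows get their
#' query coordinates swapped back, so parse -> write -> parse is the
#' identity on well-formed input.
#'
#' @param aln alignment data.frame as returned by [readBlastTab()].
#' @param file output path, or `NULL` to return the lines.
#' @return The formatted lines, invisibly when written to `file`.
#' @export
writeBlastTab <- function(aln, file = NULL) {
  qs <- ifelse(aln$reverse, aln$read_end, aln$read_start)
  qe <- ifelse(aln$reverse, aln$read_start, aln$read_end)
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%s",
                   aln$read_id, aln$ref_id,
                   formatC(aln$pident, format = "fg"),
                   aln$length, aln$mismatch, aln$gapopen,
                   qs, qe, aln$ref_start, aln$ref_end,
                   formatC(aln$evalue, format = "g"),
                   formatC(aln$bitscore, format = "fg"))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Construct a reference-to-class resolution map
#'
#' The three supported mechanisms mirror how protein reference headers
#' carry classification identity:
#' * `mode = "tag"`: scan the full header for `<tag>|<integer>` (e.g.
#'   a taxon id written as `tax|666`) and return the integer;
#' * `mode = "id"`: look the header's first whitespace-free token up in
#'   a numeric-id table;
#' * `mode = "accession"`: as `"id"`, but when the token misses, retry
#'   with its version suffix stripped (`ABC123.2` -> `ABC123`).
#'
#' @param mode one of `"tag"`, `"id"`, `"accession"`.
#' @param table named vector mapping keys to class ids (ignored in
#'   `"tag"` mode).
#' @param tag the header tag scanned for in `"tag"` mode.
#' @return A [RefClassMap].
#' @export
#' @examples
#' m <- newRefClassMap("tag", tag = "tax")
#' resolveClass(m, "gi|5|tax|666|ref protein")  # "666"
newRefClassMap <- function(mode = c("tag", "id", "accession"),
                           table = character(), tag = "tax") {
  mode <- match.arg(mode)
  tbl <- stats::setNames(as.character(table), names(table))
  new("RefClassMap", mode = mode, tag = tag, table = tbl)
}

#' Read a 2-column key -> class id mapping TSV into a RefClassMap
#'
#' @param file 2-column TSV (key, class_id); `#` comment lines skipped.
#' @param mode `"id"` or `"accession"`.
#' @return A [RefClassMap].
#' @export
readRefClassMap <- function(file, mode = c("id", "accession")) {
  mode <- match.arg(mode)
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           comment.char = "#", colClasses = "character")
  if (ncol(tab) < 2L) stop("mapping file needs 2 columns: ", file)
  newRefClassMap(mode, table = stats::setNames(tab[[2L]], tab[[1L]]))
}

#' Resolve reference headers to class ids
#'
#' Applies a [RefClassMap] to one or more reference headers. Resolution
#' is deterministic and order-independent; an unresolvable header
#' yields `NA` (absence is a value, not an error).
#'
#' @param map a [RefClassMap].
#' @param refHeader character vector of reference headers.
#' @return Character vector of class ids with `NA` where unresolved.
#' @export
resolveClass <- function(map, refHeader) {
  stopifnot(is(map, "RefClassMap"))
  if (map@mode == "tag") {
    pat <- paste0(map@tag, "\\|([0-9]+)")
    m <- regmatches(refHeader, regexpr(pat, refHeader))
    out <- rep(NA_character_, length(refHeader))
    hit <- grepl(pat, refHeader)
    out[hit] <- sub(pat, "\\1", m)
    return(out)
  }
  token <- sub("\\s.*$", "", refHeader)
  out <- unname(map@table[token])
  if (map@mode == "accession") {
    miss <- is.na(out)
    if (any(miss)) {
      stripped <- sub("\\.[0-9]+$", "", token[miss])
      out[miss] <- unname(map@table[stripped])
    }
  }
  out
}

#' Filter alignments for significance
#'
#' Per-read significance gate applied before any binning: keep rows
#' with `bitscore >= minScore`, `evalue <= maxExpected` and
#' `pident >= minPercentIdentity`; then, relative to the best
#' *surviving* score of the read, keep rows with
#' `bitscore >= (1 - topPercent/100) * best`. Reads with no surviving
#' row are dropped. Applying the filter twice is a no-op.
#'
#' Defaults follow long-standing conventions for protein-alignment
#' binning; every value is echoed into downstream output headers.
#'
#' @param aln alignment data.frame from [readBlastTab()].
#' @param minScore minimum bit score (default 50).
#' @param maxExpected maximum e-value (default 0.01).
#' @param topPercent retain scores within this percentage of the best
#'   surviving score, in `[0, 100]` (default 10).
#' @param minPercentIdentity minimum percent identity (default 0).
#' @return The filtered data.frame, rows ordered by read block and,
#'   within each read, by descending bitscore (stable).
#' @export
filterSignificant <- function(aln, minScore = 50, maxExpected = 0.01,
                              topPercent = 10, minPercentIdentity = 0) {
  if (topPercent < 0 || topPercent > 100) {
    stop("topPercent must lie in [0, 100]")
  }
  keep <- aln$bitscore >= minScore & aln$evalue <= maxExpected &
    aln$pident >= minPercentIdentity
  aln <- aln[keep, , drop = FALSE]
  if (!nrow(aln)) return(aln)
  dt <- data.table::as.data.table(aln)
  dt[, .block := match(read_id, unique(read_id))]
  dt[, .ord := seq_len(.N)]
  dt[, .best := max(bitscore), by = .block]
  dt <- dt[bitscore >= (1 - topPercent / 100) * .best]
  data.table::setorder(dt, .block, -bitscore, .ord)
  dt[, c(".block", ".ord", ".best") := NULL]
  as.data.frame(dt)
}

#' Split an alignment table into per-read groups
#'
#' @param aln alignment data.frame.
#' @return Named list of per-read data.frames, in order of first
#'   appearance.
#' @export
splitByRead <- function(aln) {
  if (!nrow(aln)) return(list())
  f <- factor(aln$read_id, levels = unique(aln$read_id))
  split(aln, f)
}
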