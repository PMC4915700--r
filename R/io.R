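.toolVersion <- function() {
  as.character(utils::packageVersion("lcabin"))
}

# provenance header lines: tool version, subcommand, full parameter set
.provenanceHeader <- function(subcommand, params) {
  vals <- vapply(params, function(v) paste(as.character(v), collapse = ","), "")
  c(sprintf("#lcabin.version=%s", .toolVersion()),
    sprintf("#subcommand=%s", subcommand),
    sprintf("#%s=%s", names(params), vals))
}

#' Write a sample profile as an indexed text table
#'
#' Output begins with `#key=value` header lines recording the tool
#' version and every parameter the profile was computed with, followed
#' by `class_id<TAB>class_name<TAB>count` rows.
#'
#' @param profile a [SampleProfile].
#' @param file output path.
#' @param labels optional named character vector mapping class ids to
#'   display names (e.g. taxon names); ids are used verbatim otherwise.
#' @param subcommand provenance label for the producing step.
#' @return `file`, invisibly.
#' @export
writeProfile <- function(profile, file, labels = NULL,
                         subcommand = "bin") {
  ids <- names(profile@counts)
  nm <- if (is.null(labels)) ids else {
    out <- unname(labels[ids])
    ifelse(is.na(out), ids, out)
  }
  params <- c(list(sample = profile@sampleName,
                   classification = profile@classificationName,
                   totalReads = profile@totalReads),
              profile@parameters)
  lines <- c(.provenanceHeader(subcommand, params),
             sprintf("%s\t%s\t%s", ids, nm,
                     formatC(profile@counts, format = "fg")))
  writeLines(lines, file)
  invisible(file)
}

#' Read a sample profile written by [writeProfile()]
#'
#' @param file path to the profile TSV.
#' @return A [SampleProfile]; header parameters are restored into the
#'   `parameters` slot (as character).
#' @export
readProfile <- function(file) {
  lines <- readLines(file, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- sub("^#", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  params <- stats::setNames(as.list(vals), keys)
  parts <- strsplit(body, "\t", fixed = TRUE)
  counts <- stats::setNames(
    as.numeric(vapply(parts, `[`, "", 3L)),
    vapply(parts, `[`, "", 1L))
  totalReads <- if ("totalReads" %in% keys) {
    as.integer(params$totalReads)
  } else {
    as.integer(round(sum(counts)))
  }
  drop <- c("lcabin.version", "subcommand", "sample", "classification",
            "totalReads")
  new("SampleProfile",
      sampleName = if ("sample" %in% keys) params$sample else basename(file),
      classificationName = if ("classification" %in% keys)
        params$classification else "Taxonomy",
      counts = counts, totalReads = totalReads,
      parameters = params[setdiff(keys, drop)])
}

#' Export a comparison document as a wide classes-by-samples TSV
#'
#' @param doc a [ComparisonDocument].
#' @param file output path.
#' @param subcommand provenance label.
#' @return `file`, invisibly.
#' @export
writeComparison <- function(doc, file, subcommand = "compare") {
  params <- list(classification = doc@classificationName,
                 normalization = doc@normalization,
                 samples = paste(doc@samples, collapse = ","))
  header <- paste(c("class_id", doc@samples), collapse = "\t")
  rows <- apply(doc@matrix, 1L, function(x)
    paste(formatC(x, format = "fg"), collapse = "\t"))
  lines <- c(.provenanceHeader(subcommand, params), header,
             paste(rownames(doc@matrix), rows, sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Export a distance matrix as a square labeled TSV
#'
#' @param d a [DistanceMatrix].
#' @param file output path.
#' @param subcommand provenance label.
#' @return `file`, invisibly.
#' @export
writeDistance <- function(d, file, subcommand = "pcoa") {
  lines <- c(.provenanceHeader(subcommand, list(samples = length(d@labels))),
             paste(c("sample", d@labels), collapse = "\t"),
             vapply(seq_along(d@labels), function(i) {
               paste(c(d@labels[i],
                       formatC(d@values[i, ], format = "g", digits = 10)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, file)
  invisible(file)
}

#' Export an ordination: coordinates plus eigenvalue table
#'
#' @param ord an [Ordination].
#' @param file output path.
#' @param params extra provenance parameters.
#' @return `file`, invisibly.
#' @export
writeOrdination <- function(ord, file, params = list()) {
  k <- ncol(ord@coordinates)
  lines <- c(
    .provenanceHeader("pcoa", c(params, list(
      axes = k,
      eigenvalues = paste(formatC(ord@eigenvalues, format = "g", digits = 8),
                          collapse = ","),
      fractionExplained = paste(formatC(ord@fractionExplained,
                                        format = "g", digits = 8),
                                collapse = ",")))),
    paste(c("sample", colnames(ord@coordinates)), collapse = "\t"),
    vapply(seq_len(nrow(ord@coordinates)), function(i) {
      paste(c(rownames(ord@coordinates)[i],
              formatC(ord@coordinates[i, ], format = "g", digits = 10)),
            collapse = "\t")
    }, ""))
  writeLines(lines, file)
  invisible(file)
}

#' Dump a classification tree as a node table
#'
#' Rows are `class_id<TAB>parent_id<TAB>label` with `ROOT` marking
#' tier-1 nodes; the inverse of [loadHierarchy()] for generic trees.
#'
#' @param ct a [ClassificationTree].
#' @param file output path.
#' @param subcommand provenance label.
#' @return `file`, invisibly.
#' @export
writeHierarchy <- function(ct, file, subcommand = "classify-tree") {
  parent <- ifelse(is.na(ct@parentId), "ROOT", ct@parentId)
  lines <- c(.provenanceHeader(subcommand,
                               list(classification = ct@name,
                                    nodes = length(ct@nodeId))),
             sprintf("%s\t%s\t%s", ct@nodeId, parent, ct@label))
  writeLines(lines, file)
  invisible(file)
}
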