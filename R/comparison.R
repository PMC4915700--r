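#' Merge per-sample profiles into a comparison document
#'
#' Combines any number of [SampleProfile]s over the union of their
#' class ids into a single class-by-sample count matrix, and merges the
#' supplied metadata tables into one table keyed by sample, with
#' attribute-name collisions merged by name and absent cells left `NA`.
#'
#' @param profiles list of [SampleProfile] objects sharing one
#'   classification; sample names must be unique.
#' @param metadata optional list of data.frames (rownames = sample
#'   names) or a single data.frame, e.g. from [readMetadataCSV()].
#' @return A [ComparisonDocument] with `normalization = "none"`.
#' @export
mergeSamples <- function(profiles, metadata = list()) {
  if (!length(profiles)) stop("no profiles to merge")
  classif <- unique(vapply(profiles, function(p) p@classificationName, ""))
  if (length(classif) != 1L) {
    stop("cannot merge mixed classifications: ",
         paste(classif, collapse = ", "))
  }
  samples <- vapply(profiles, function(p) p@sampleName, "")
  if (anyDuplicated(samples)) {
    stop("duplicate sample name '", samples[anyDuplicated(samples)], "'")
  }
  classes <- sort(unique(unlist(lapply(profiles, function(p) names(p@counts)))))
  mat <- matrix(0, nrow = length(classes), ncol = length(samples),
                dimnames = list(classes, samples))
  for (p in profiles) mat[names(p@counts), p@sampleName] <- p@counts
  if (is.data.frame(metadata)) metadata <- list(metadata)
  meta <- data.frame(row.names = samples)
  for (m in metadata) {
    for (attribute in colnames(m)) {
      if (!attribute %in% colnames(meta)) meta[[attribute]] <- NA
      hit <- intersect(rownames(m), samples)
      meta[hit, attribute] <- m[hit, attribute]
    }
  }
  new("ComparisonDocument", samples = samples,
      classificationName = classif, matrix = mat,
      normalization = "none", metadata = meta,
      parameters = stats::setNames(lapply(profiles, function(p) p@parameters),
                                   samples))
}

#' Classified totals of each sample in a document
#'
#' Sums counts per sample, excluding the bookkeeping bins
#' ([UNASSIGNED], [UNRESOLVED]).
#'
#' @param doc a [ComparisonDocument].
#' @return Named numeric vector of classified read totals.
#' @export
classifiedTotals <- function(doc) {
  keep <- !rownames(doc@matrix) %in% c(UNASSIGNED, UNRESOLVED)
  colSums(doc@matrix[keep, , drop = FALSE])
}

#' Normalize all samples to the smallest classified total
#'
#' Scales each sample's counts by
#' `min(classified totals) / (its classified total)`, making samples
#' comparable despite unequal sequencing depth. Counts become reals;
#' re-application is the identity.
#'
#' @param doc a [ComparisonDocument].
#' @return The document with scaled counts and
#'   `normalization = "to-smallest"`.
#' @export
normalizeToSmallest <- function(doc) {
  totals <- classifiedTotals(doc)
  if (any(totals <= 0)) {
    stop("sample '", names(totals)[totals <= 0][1L],
         "' has no classified reads; cannot normalize")
  }
  scale <- min(totals) / totals
  doc@matrix <- sweep(doc@matrix, 2L, scale, "*")
  doc@normalization <- "to-smallest"
  doc
}

#' Extract one sample back out of a document
#'
#' @param doc a [ComparisonDocument].
#' @param sample sample name.
#' @return A [SampleProfile] with the sample's nonzero classes.
#' @export
extractSample <- function(doc, sample) {
  if (!sample %in% doc@samples) stop("unknown sample '", sample, "'")
  counts <- doc@matrix[, sample]
  counts <- counts[counts != 0]
  params <- doc@parameters[[sample]]
  new("SampleProfile", sampleName = sample,
      classificationName = doc@classificationName,
      counts = counts,
      totalReads = as.integer(round(sum(counts))),
      parameters = if (is.null(params)) list() else params)
}

#' Total biome: the union of all samples
#'
#' @param doc a [ComparisonDocument].
#' @return A [SampleProfile] with per-class sums over all samples.
#' @export
totalBiome <- function(doc) {
  counts <- rowSums(doc@matrix)
  counts <- counts[counts != 0]
  new("SampleProfile", sampleName = "total-biome",
      classificationName = doc@classificationName, counts = counts,
      totalReads = as.integer(round(sum(counts))),
      parameters = list(kind = "total-biome"))
}

#' Core biome: classes present in a minimum fraction of samples
#'
#' A class is "present" in a sample when its count is at least
#' `detectionMin`; it belongs to the core when present in at least
#' `ceiling(minFractionOfSamples * nSamples)` samples. Output counts
#' sum each core class over the samples in which it is present.
#'
#' @param doc a [ComparisonDocument].
#' @param minFractionOfSamples required prevalence, in `(0, 1]`.
#' @param detectionMin minimum count for presence (default 1).
#' @return A [SampleProfile] over the core classes.
#' @export
coreBiome <- function(doc, minFractionOfSamples, detectionMin = 1) {
  if (minFractionOfSamples <= 0 || minFractionOfSamples > 1) {
    stop("minFractionOfSamples must lie in (0, 1]")
  }
  present <- doc@matrix >= detectionMin
  need <- ceiling(minFractionOfSamples * length(doc@samples))
  core <- rowSums(present) >= need
  counts <- rowSums(doc@matrix * present)[core]
  new("SampleProfile", sampleName = "core-biome",
      classificationName = doc@classificationName, counts = counts,
      totalReads = as.integer(round(sum(counts))),
      parameters = list(kind = "core-biome",
                        minFractionOfSamples = minFractionOfSamples,
                        detectionMin = detectionMin))
}

#' Merge samples by the values of a metadata attribute
#'
#' Produces one pseudo-sample per distinct attribute value, with counts
#' summed within each group. Samples with an absent value form the
#' `"NA"` group.
#'
#' @param doc a [ComparisonDocument].
#' @param attribute metadata attribute name.
#' @return A [ComparisonDocument] over the pseudo-samples; its metadata
#'   records the group value and member count.
#' @export
groupByAttribute <- function(doc, attribute) {
  if (!attribute %in% colnames(doc@metadata)) {
    stop("unknown metadata attribute '", attribute, "'")
  }
  values <- as.character(doc@metadata[doc@samples, attribute])
  values[is.na(values)] <- "NA"
  groups <- unique(values)
  mat <- vapply(groups, function(g) {
    rowSums(doc@matrix[, values == g, drop = FALSE])
  }, numeric(nrow(doc@matrix)))
  mat <- matrix(mat, nrow = nrow(doc@matrix),
                dimnames = list(rownames(doc@matrix), groups))
  meta <- data.frame(row.names = groups,
                     groupedBy = rep(attribute, length(groups)),
                     nSamples = as.integer(table(factor(values, groups))))
  new("ComparisonDocument", samples = groups,
      classificationName = doc@classificationName, matrix = mat,
      normalization = doc@normalization, metadata = meta,
      parameters = list(groupedBy = attribute))
}

#' Read a sample metadata CSV
#'
#' Standard metadata dialect: first column `#SampleID`, remaining
#' columns arbitrary attributes; comma-separated, UTF-8, standard
#' quoting.
#'
#' @param file path to the CSV.
#' @return data.frame of attributes with sample ids as rownames.
#' @export
readMetadataCSV <- function(file) {
  tab <- utils::read.csv(file, check.names = FALSE, comment.char = "")
  first <- colnames(tab)[1L]
  if (!first %in% c("#SampleID", "SampleID", "X.SampleID")) {
    stop("metadata CSV must start with a #SampleID column, found '",
         first, "'")
  }
  out <- tab[, -1L, drop = FALSE]
  rownames(out) <- as.character(tab[[1L]])
  out
}

#' Write a sample metadata CSV
#'
#' @param meta data.frame with sample ids as rownames.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeMetadataCSV <- function(meta, file) {
  out <- cbind(`#SampleID` = rownames(meta), meta)
  utils::write.csv(out, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

setMethod("show", "ComparisonDocument", function(object) {
  cat(sprintf(paste0("ComparisonDocument (%s): %d samples x %d classes,",
                     " normalization=%s, %d metadata attributes\n"),
              object@classificationName, length(object@samples),
              nrow(object@matrix), object@normalization,
              ncol(object@metadata)))
})
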