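.docCounts <- function(doc) {
  keep <- !rownames(doc@matrix) %in% c(UNASSIGNED, UNRESOLVED)
  doc@matrix[keep, , drop = FALSE]
}

.newDistance <- function(values, labels) {
  values <- (values + t(values)) / 2          # kill rounding asymmetry
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  new("DistanceMatrix", labels = labels, values = values)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over the class union;
#' bounded by `[0, 1]`, 0 for identical samples, 1 for disjoint
#' supports. Distances are computed on the document's counts as given
#' (raw or normalized); normalization is the caller's explicit step.
#'
#' @param doc a [ComparisonDocument] with at least 2 samples.
#' @return A [DistanceMatrix].
#' @export
brayCurtis <- function(doc) {
  m <- .docCounts(doc)
  if (any(m < 0)) stop("negative counts")
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    denom <- sum(m[, i] + m[, j])
    if (denom == 0) {
      stop("Bray-Curtis undefined for two all-zero samples: ",
           doc@samples[i], ", ", doc@samples[j])
    }
    d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / denom
  }
  .newDistance(d, doc@samples)
}

#' Jensen-Shannon distance between samples
#'
#' Samples are normalized to probability vectors; the Jensen-Shannon
#' divergence is computed with the natural logarithm (`0 * log 0 := 0`)
#' and the distance is its square root, so disjoint distributions are
#' `sqrt(ln 2)` apart.
#'
#' @param doc a [ComparisonDocument].
#' @return A [DistanceMatrix].
#' @export
jensenShannon <- function(doc) {
  m <- .docCounts(doc)
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("all-zero sample: ", doc@samples[totals <= 0][1L])
  }
  p <- sweep(m, 2L, totals, "/")
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  n <- ncol(p)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    mid <- (p[, i] + p[, j]) / 2
    div <- sum(xlx(p[, i]) + xlx(p[, j]) - 2 * xlx(mid)) / 2
    d[i, j] <- d[j, i] <- sqrt(max(div, 0))
  }
  .newDistance(d, doc@samples)
}

#' Euclidean distance between sample count vectors
#'
#' Plain L2 distance on the count vectors; principal coordinates of
#' this matrix coincide with a principal component analysis of the
#' centered counts.
#'
#' @param doc a [ComparisonDocument].
#' @return A [DistanceMatrix].
#' @export
euclideanDistance <- function(doc) {
  m <- .docCounts(doc)
  d <- as.matrix(stats::dist(t(m), method = "euclidean"))
  .newDistance(unname(d), doc@samples)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: the squared distance matrix is
#' double-centered (`B = -1/2 * J %*% D^2 %*% J` with `J` the centering
#' projector), eigendecomposed, and coordinates are eigenvectors scaled
#' by the square roots of the positive eigenvalues. Axis signs are
#' fixed by forcing the largest-magnitude coordinate on each axis
#' positive, making results reproducible across eigensolvers. Negative
#' eigenvalues (possible for non-Euclidean dissimilarities) are
#' excluded from the explained-fraction denominator with a warning.
#'
#' @param d a [DistanceMatrix].
#' @param k number of axes to keep, `2 <= k <= n - 1`; truncated with a
#'   warning if it exceeds the number of positive eigenvalues.
#' @return An [Ordination].
#' @export
pcoa <- function(d, k = 2L) {
  n <- length(d@labels)
  if (k < 1L) stop("k must be >= 1")
  if (k > n - 1L) {
    warning(sprintf("k=%d exceeds n-1=%d axes; truncated", k, n - 1L))
    k <- n - 1L
  }
  D2 <- d@values^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- eig$values
  tol <- 1e-9 * max(1, abs(ev[1L]))
  npos <- sum(ev > tol)
  if (any(ev < -tol)) {
    warning(sprintf("%d negative eigenvalue(s) excluded (non-Euclidean input)",
                    sum(ev < -tol)))
  }
  if (k > npos) {
    warning(sprintf("k=%d exceeds %d positive eigenvalue(s); truncated", k, npos))
    k <- npos
  }
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  for (j in seq_len(k)) {
    if (coords[which.max(abs(coords[, j])), j] < 0) {
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- d@labels
  colnames(coords) <- paste0("PCo", seq_len(k))
  new("Ordination", coordinates = coords, eigenvalues = ev,
      fractionExplained = ev[seq_len(k)] / sum(ev[ev > tol]))
}

# shared worker for bi-plot / tri-plot vectors: correlation of each
# variable with each ordination axis, scaled by the variable's share of
# total standard deviation; ranked by vector length
.loadingVectors <- function(vars, ord, nTop) {
  if (nTop < 1L) stop("nTop must be >= 1")
  coords <- ord@coordinates
  sds <- apply(vars, 1L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds > 0
  vars <- vars[keep, , drop = FALSE]
  sds <- sds[keep]
  if (!nrow(vars)) {
    return(data.frame(id = character(0)))
  }
  share <- sds / sum(sds)
  vec <- matrix(0, nrow(vars), ncol(coords),
                dimnames = list(rownames(vars), colnames(coords)))
  for (j in seq_len(ncol(coords))) {
    cj <- apply(vars, 1L, function(x) {
      suppressWarnings(stats::cor(x, coords[, j],
                                  use = "pairwise.complete.obs"))
    })
    cj[is.na(cj)] <- 0
    vec[, j] <- cj * share
  }
  len <- sqrt(rowSums(vec^2))
  ord2 <- order(-len, rownames(vec))
  pick <- ord2[seq_len(min(nTop, length(ord2)))]
  out <- data.frame(id = rownames(vec)[pick], length = len[pick],
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(vec[pick, , drop = FALSE], row.names = NULL))
}

#' Bi-plot vectors: classes driving the ordination
#'
#' For each class, component `j` is the Pearson correlation between the
#' class's per-sample relative abundances and the samples' axis-`j`
#' coordinates, scaled by the class's share of total standard
#' deviation; the vector points in the direction of steepest increase
#' of that class across the plot. Classes are ranked by vector length
#' (ties by ascending class id) and the top `nTop` returned; the
#' default of 5 matches the usual "top five bi-vectors" display.
#' Zero-variance classes are excluded.
#'
#' @param doc the [ComparisonDocument] the ordination was computed
#'   from, samples in identical order.
#' @param ord an [Ordination].
#' @param nTop number of vectors to return (default 5).
#' @return data.frame `(id, length, PCo1, ..., PCok)`.
#' @export
biplotVectors <- function(doc, ord, nTop = 5L) {
  if (!identical(rownames(ord@coordinates), doc@samples)) {
    stop("ordination samples disagree with document samples")
  }
  m <- .docCounts(doc)
  totals <- colSums(m)
  if (any(totals <= 0)) stop("all-zero sample in document")
  rel <- sweep(m, 2L, totals, "/")
  .loadingVectors(rel, ord, nTop)
}

#' Tri-plot vectors: numeric metadata driving the ordination
#'
#' As [biplotVectors()], but over the numeric metadata attributes of
#' the document; non-numeric attributes are skipped with a message, and
#' an empty result with a warning is returned when no numeric attribute
#' exists.
#'
#' @inheritParams biplotVectors
#' @return data.frame `(id, length, PCo1, ..., PCok)`.
#' @export
triplotVectors <- function(doc, ord, nTop = 5L) {
  if (!identical(rownames(ord@coordinates), doc@samples)) {
    stop("ordination samples disagree with document samples")
  }
  meta <- doc@metadata[doc@samples, , drop = FALSE]
  numeric_ok <- vapply(meta, is.numeric, logical(1))
  skipped <- colnames(meta)[!numeric_ok]
  if (length(skipped)) {
    message("skipping non-numeric attribute(s): ",
            paste(skipped, collapse = ", "))
  }
  if (!any(numeric_ok)) {
    warning("no numeric metadata attributes; empty tri-plot")
    return(data.frame(id = character(0)))
  }
  vars <- t(as.matrix(meta[, numeric_ok, drop = FALSE]))
  .loadingVectors(vars, ord, nTop)
}

#' Alpha diversity of one sample profile
#'
#' Standard indices over the profile's relative abundances `p_i`
#' (bookkeeping bins excluded): Shannon entropy `-sum p_i ln p_i`,
#' Simpson's index `1 - sum p_i^2`, and richness (number of classes
#' with nonzero count).
#'
#' @param profile a [SampleProfile] with positive classified total.
#' @param index one of `"shannon"`, `"simpson"`, `"richness"`.
#' @return A single number.
#' @export
alphaDiversity <- function(profile, index = c("shannon", "simpson",
                                              "richness")) {
  index <- match.arg(index)
  counts <- profile@counts[!names(profile@counts) %in%
                             c(UNASSIGNED, UNRESOLVED)]
  counts <- counts[counts > 0]
  if (!length(counts) || sum(counts) <= 0) {
    stop("alpha diversity undefined for an empty profile")
  }
  p <- counts / sum(counts)
  switch(index,
         shannon = -sum(p * log(p)),
         simpson = 1 - sum(p^2),
         richness = length(p))
}

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix over %d samples (max %.4g)\n",
              length(object@labels), max(object@values)))
})

setMethod("show", "Ordination", function(object) {
  cat(sprintf("Ordination: %d samples x %d axes (%.1f%% explained)\n",
              nrow(object@coordinates), ncol(object@coordinates),
              100 * sum(object@fractionExplained)))
})
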