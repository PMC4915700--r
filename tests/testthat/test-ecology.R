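twoDoc <- function(x, y, names = c("s1", "s2")) {
  classes <- paste0("c", seq_along(x))
  mergeSamples(list(profileOf(names[1L], stats::setNames(x, classes)),
                    profileOf(names[2L], stats::setNames(y, classes))))
}

test_that("Bray-Curtis matches the hand example and its bounds", {
  expect_equal(brayCurtis(twoDoc(c(2, 1, 0), c(1, 1, 1)))@values[1, 2],
               2 / 6)
  expect_equal(brayCurtis(twoDoc(c(3, 1), c(3, 1)))@values[1, 2], 0)
  expect_equal(brayCurtis(twoDoc(c(3, 0), c(0, 4)))@values[1, 2], 1)
})

test_that("distance matrices agree with the vegan oracle on random counts", {
  set.seed(8)
  counts <- matrix(rpois(60, 20), nrow = 10)
  profiles <- lapply(1:6, function(j)
    profileOf(paste0("s", j), stats::setNames(counts[, j], paste0("c", 1:10))))
  doc <- mergeSamples(profiles)
  bc <- brayCurtis(doc)@values
  ref <- as.matrix(vegan::vegdist(t(counts), method = "bray"))
  expect_equal(unname(bc), unname(ref), tolerance = 1e-12)
  eu <- euclideanDistance(doc)@values
  refEu <- as.matrix(stats::dist(t(counts)))
  expect_equal(unname(eu), unname(refEu), tolerance = 1e-12)
})

test_that("Jensen-Shannon has the closed-form disjoint value and symmetry", {
  expect_equal(jensenShannon(twoDoc(c(1, 0), c(0, 1)))@values[1, 2],
               sqrt(log(2)))
  expect_equal(jensenShannon(twoDoc(c(2, 2), c(1, 1)))@values[1, 2], 0)
  set.seed(9)
  for (rep in 1:10) {
    x <- rpois(5, 10) + 1
    y <- rpois(5, 10) + 1
    d1 <- jensenShannon(twoDoc(x, y))@values[1, 2]
    d2 <- jensenShannon(twoDoc(y, x))@values[1, 2]
    expect_equal(d1, d2)
  }
})

test_that("all distances satisfy metric-style axioms on random documents", {
  set.seed(10)
  counts <- matrix(rpois(40, 15) + 1, nrow = 8)
  doc <- mergeSamples(lapply(1:5, function(j)
    profileOf(paste0("s", j), stats::setNames(counts[, j], paste0("c", 1:8)))))
  for (fn in list(brayCurtis, jensenShannon, euclideanDistance)) {
    d <- fn(doc)@values
    expect_true(all(diag(d) == 0))
    expect_lt(max(abs(d - t(d))), 1e-12)
    expect_true(all(d >= 0))
  }
  expect_true(all(brayCurtis(doc)@values <= 1))
})

test_that("pcoa reconstructs Euclidean distances and matches a PCA oracle", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  rownames(pts) <- paste0("s", 1:3)
  d <- new("DistanceMatrix", labels = rownames(pts),
           values = unname(as.matrix(stats::dist(pts))))
  o <- pcoa(d, 2L)
  expect_equal(unname(as.matrix(stats::dist(o@coordinates))),
               unname(d@values), tolerance = 1e-9)
  # PCA equivalence on random planar point clouds, up to the sign
  # convention; with k matching the point dimension the embedding is
  # exact
  set.seed(12)
  for (rep in 1:10) {
    x <- matrix(rnorm(7 * 2), nrow = 7,
                dimnames = list(paste0("s", 1:7), NULL))
    dm <- new("DistanceMatrix", labels = rownames(x),
              values = unname(as.matrix(stats::dist(x))))
    o2 <- pcoa(dm, 2L)
    expect_equal(unname(as.matrix(stats::dist(o2@coordinates))),
                 unname(dm@values), tolerance = 1e-9)
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    for (j in 1:2) {
      a <- o2@coordinates[, j]
      b <- pc$x[, j]
      expect_equal(abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2))), 1,
                   tolerance = 1e-6)
    }
    expect_true(all(o2@eigenvalues > -1e-9 * max(abs(o2@eigenvalues))))
  }
})

test_that("two samples yield a single axis at half the distance each", {
  doc <- twoDoc(c(4, 0), c(0, 4))
  d <- euclideanDistance(doc)
  o <- suppressWarnings(pcoa(d, 2L))
  expect_equal(ncol(o@coordinates), 1L)
  expect_equal(sort(abs(o@coordinates[, 1])),
               rep(d@values[1, 2] / 2, 2), ignore_attr = TRUE)
})

test_that("pcoa matches the cmdscale oracle up to axis signs", {
  set.seed(14)
  x <- matrix(rnorm(6 * 4), nrow = 6, dimnames = list(paste0("s", 1:6), NULL))
  dm <- new("DistanceMatrix", labels = rownames(x),
            values = unname(as.matrix(stats::dist(x))))
  o <- pcoa(dm, 3L)
  ref <- stats::cmdscale(stats::as.dist(dm@values), k = 3)
  for (j in 1:3) {
    expect_equal(abs(o@coordinates[, j]), abs(ref[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("biplot vectors rank the class that separates two groups first", {
  # two clusters of samples separated by class c1 only
  profiles <- c(
    lapply(1:3, function(j) profileOf(paste0("a", j),
      c(c1 = 100 + j, c2 = 50, c3 = 48 + j))),
    lapply(1:3, function(j) profileOf(paste0("b", j),
      c(c1 = 5 + j, c2 = 50, c3 = 47 + j))))
  doc <- mergeSamples(profiles)
  ord <- suppressWarnings(pcoa(brayCurtis(doc), 2L))
  vec <- biplotVectors(doc, ord, 3L)
  expect_equal(vec$id[1L], "c1")
  expect_error(biplotVectors(doc, ord, 0L), "nTop")
})

test_that("classes with zero relative-abundance variance are excluded", {
  # every sample is a scaled copy of the same composition, so all
  # relative abundances are constant
  profiles <- lapply(1:4, function(j)
    profileOf(paste0("s", j), c(c1 = 10 * j, c2 = 30 * j)))
  doc <- mergeSamples(profiles)
  ord <- suppressWarnings(pcoa(euclideanDistance(doc), 2L))
  vec <- biplotVectors(doc, ord, 5L)
  expect_equal(nrow(vec), 0L)
})

test_that("biplot ranking is invariant under per-sample rescaling", {
  set.seed(15)
  counts <- matrix(rpois(36, 30) + 1, nrow = 6,
                   dimnames = list(paste0("c", 1:6), NULL))
  mk <- function(scales) mergeSamples(lapply(1:6, function(j)
    profileOf(paste0("s", j), counts[, j] * scales[j])))
  d1 <- mk(rep(1, 6)); d2 <- mk(c(2, 5, 1, 3, 10, 4))
  o1 <- suppressWarnings(pcoa(brayCurtis(normalizeToSmallest(d1)), 2L))
  v1 <- biplotVectors(normalizeToSmallest(d1), o1, 6L)
  o2 <- suppressWarnings(pcoa(brayCurtis(normalizeToSmallest(d2)), 2L))
  v2 <- biplotVectors(normalizeToSmallest(d2), o2, 6L)
  expect_equal(v1$id, v2$id)
})

test_that("triplot vectors use numeric attributes and skip the rest", {
  profiles <- lapply(1:4, function(j)
    profileOf(paste0("s", j), c(c1 = 10 * j, c2 = 50 - 10 * j)))
  meta <- data.frame(row.names = paste0("s", 1:4),
                     depth = c(1, 2, 3, 4), site = c("x", "x", "y", "y"))
  doc <- mergeSamples(profiles, meta)
  ord <- suppressWarnings(pcoa(brayCurtis(doc), 2L))
  tri <- suppressMessages(triplotVectors(doc, ord, 5L))
  expect_equal(tri$id, "depth")
  noNum <- mergeSamples(profiles,
                        data.frame(row.names = paste0("s", 1:4),
                                   site = c("x", "x", "y", "y")))
  expect_warning(out <- suppressMessages(triplotVectors(noNum, ord, 5L)),
                 "no numeric")
  expect_equal(nrow(out), 0L)
})

test_that("alpha diversity matches closed forms and the vegan oracle", {
  expect_equal(alphaDiversity(profileOf("u", c(a = 1, b = 1)), "shannon"),
               log(2))
  p3 <- profileOf("u", c(a = 2, b = 1, c = 1))
  expect_equal(alphaDiversity(p3, "shannon"), 1.5 * log(2))
  one <- profileOf("u", c(a = 5))
  expect_equal(alphaDiversity(one, "shannon"), 0)
  expect_equal(alphaDiversity(one, "simpson"), 0)
  expect_equal(alphaDiversity(one, "richness"), 1)
  set.seed(16)
  x <- rpois(12, 9) + 1
  prof <- profileOf("v", stats::setNames(x, paste0("c", seq_along(x))))
  expect_equal(alphaDiversity(prof, "shannon"),
               unname(vegan::diversity(x, "shannon")))
  expect_equal(alphaDiversity(prof, "simpson"),
               unname(vegan::diversity(x, "simpson")))
})
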