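tagMap <- newRefClassMap("tag", tag = "tax")

test_that("naive LCA assigns singletons, siblings and the empty case", {
  tax <- forkTaxonomy()
  one <- rbind(alnRow("r1", "x tax|11|", 90), alnRow("r1", "y tax|11|", 80))
  expect_equal(naiveLCA(one, tax, tagMap)$class_id, "11")
  sib <- rbind(alnRow("r1", "x tax|11|", 90), alnRow("r1", "y tax|12|", 85))
  expect_equal(naiveLCA(sib, tax, tagMap)$class_id, "10")
  none <- alnRow("r1", "no tag here", 90)
  out <- naiveLCA(none, tax, tagMap)
  expect_equal(out$class_id, UNASSIGNED)
  expect_equal(attr(out, "unresolvedRecords"), 1L)
})

test_that("naive LCA agrees with the path-intersection oracle on random input", {
  set.seed(99)
  for (rep in 1:40) {
    tax <- randomTaxonomy(sample(10:120, 1L))
    taxa <- sample(tax@ids, sample(1:5, 1L), replace = TRUE)
    aln <- do.call(rbind, lapply(seq_along(taxa), function(j) {
      alnRow("r1", sprintf("ref%d tax|%d|", j, taxa[j]), 60 + j)
    }))
    expect_equal(naiveLCA(aln, tax, tagMap)$class_id,
                 as.character(lcaOracle(tax, unique(taxa))))
  }
})

test_that("reference weights follow the two-phase rule with a weight floor", {
  tax <- forkTaxonomy()
  # r1 aligns only to S11a; r2 aligns to S11a+S11b (same species 11);
  # r3 spans species 11 and 12 -> contributes nothing
  aln <- rbind(alnRow("r1", "S11a tax|11|", 90),
               alnRow("r2", "S11a tax|11|", 90),
               alnRow("r2", "S11b tax|11|", 88),
               alnRow("r3", "S11a tax|11|", 90),
               alnRow("r3", "S12 tax|12|", 89))
  w <- computeRefWeights(aln, tax, tagMap)
  expect_equal(unname(w$weights[c("S11a tax|11|", "S11b tax|11|")]),
               c(2L, 1L))
  expect_equal(unname(w$weights["S12 tax|12|"]), 1L)  # floor
  expect_equal(unname(w$speciesOf["S11a tax|11|"]), 11L)
})

test_that("species equivalence falls back to the taxon itself above species", {
  tax <- forkTaxonomy()
  aln <- rbind(alnRow("r1", "G tax|10|", 90))  # genus-level reference
  w <- computeRefWeights(aln, tax, tagMap)
  expect_equal(unname(w$speciesOf["G tax|10|"]), 10L)
  expect_equal(unname(w$weights["G tax|10|"]), 1L)
})

test_that("weighted LCA places by subtree weight coverage", {
  tax <- forkTaxonomy()
  aln <- rbind(alnRow("r1", "S11 tax|11|", 90),
               alnRow("r1", "S12 tax|12|", 90))
  w91 <- list(weights = c("S11 tax|11|" = 9L, "S12 tax|12|" = 1L))
  expect_equal(weightedLCA(aln, w91, tax, tagMap, 0.75)$class_id, "11")
  w64 <- list(weights = c("S11 tax|11|" = 6L, "S12 tax|12|" = 4L))
  expect_equal(weightedLCA(aln, w64, tax, tagMap, 0.75)$class_id, "10")
  # single reference: placed on its taxon regardless of coverage
  one <- alnRow("r1", "S21 tax|21|", 90)
  w1 <- list(weights = c("S21 tax|21|" = 1L))
  expect_equal(weightedLCA(one, w1, tax, tagMap, 0.99)$class_id, "21")
  expect_error(weightedLCA(aln, w91, tax, tagMap, 0.5), "coverage")
})

test_that("weighted LCA at coverage 1 reduces to naive LCA on single-species reads", {
  set.seed(13)
  tax <- randomTaxonomy(60)
  for (rep in 1:20) {
    t1 <- sample(tax@ids, 1L)
    aln <- rbind(alnRow("r1", sprintf("a tax|%d|", t1), 80),
                 alnRow("r1", sprintf("b tax|%d|", t1), 75))
    w <- computeRefWeights(aln, tax, tagMap)
    expect_equal(weightedLCA(aln, w, tax, tagMap, coverage = 1)$class_id,
                 naiveLCA(aln, tax, tagMap)$class_id)
  }
})

test_that("min-support promotes weak nodes to their parents, cascading", {
  tax <- ladderTaxonomy()
  mkAssign <- function(nodes) {
    data.frame(read_id = sprintf("r%03d", seq_along(nodes)),
               class_id = as.character(nodes), algorithm = "naive-lca",
               score_used = 60, stringsAsFactors = FALSE)
  }
  # threshold 1 is the identity
  a <- mkAssign(c(4, 4, 5))
  expect_equal(minSupportFilter(a, tax, 1L), a)
  # 2 reads on species, 10 on genus, threshold 3 -> species reads move up
  b <- mkAssign(c(rep(4, 2), rep(3, 10)))
  fb <- minSupportFilter(b, tax, 3L)
  expect_equal(sum(fb$class_id == "3"), 12L)
  # cascade: 1 read at strain, 1 at species, 1 at genus, threshold 3:
  # all three end on the first ancestor meeting the threshold
  c3 <- mkAssign(c(5, 4, 3))
  fc <- minSupportFilter(c3, tax, 3L)
  expect_equal(unique(fc$class_id), "3")
  # re-application is the identity
  expect_equal(minSupportFilter(fc, tax, 3L), fc)
})

test_that("min-support output has no populated node below threshold", {
  set.seed(21)
  for (rep in 1:15) {
    tax <- randomTaxonomy(40)
    nodes <- sample(tax@ids, 30L, replace = TRUE)
    a <- data.frame(read_id = sprintf("r%03d", seq_along(nodes)),
                    class_id = as.character(nodes),
                    algorithm = "naive-lca", score_used = 60)
    thr <- sample(2:5, 1L)
    f <- minSupportFilter(a, tax, thr)
    counts <- countAssignments(f)
    for (id in as.integer(names(counts))) {
      onOrBelow <- sum(counts[vapply(as.integer(names(counts)),
                                     function(x) isAncestorOrSelf(tax, id, x),
                                     logical(1))])
      expect_true(onOrBelow >= thr || id == tax@rootId)
    }
    expect_equal(minSupportFilter(f, tax, thr), f)
  }
})

test_that("projection pushes counts down by the worked apportionment", {
  # root(1) -> t(2) -> c1(3), c2(4); species below each child carry the
  # on-or-below weights 30 and 10; 10 reads sit on t
  tax <- newTaxonomy(ids = c(1L, 2L, 3L, 4L, 5L, 6L),
                     parent = c(1L, 1L, 2L, 2L, 3L, 4L),
                     rank = c("root", "phylum", "genus", "genus",
                              "species", "species"))
  counts <- c(`2` = 10, `5` = 30, `6` = 10)
  out <- projectToRank(counts, tax, "species")
  expect_equal(out[["5"]], 38)   # 30 + 7.5 -> 8 by largest remainder
  expect_equal(out[["6"]], 12)   # 10 + 2.5 -> 2
  expect_equal(sum(out), 50)
})

test_that("apportionment fraction ties break toward the smaller taxon id", {
  tax <- newTaxonomy(ids = c(1L, 2L, 3L, 4L),
                     parent = c(1L, 1L, 2L, 2L),
                     rank = c("root", "genus", "species", "species"))
  # equal child weights, odd count: extra read goes to taxon 3
  counts <- c(`2` = 5, `3` = 1, `4` = 1)
  out <- projectToRank(counts, tax, "species")
  expect_equal(out[["3"]], 4)
  expect_equal(out[["4"]], 3)
})

test_that("projection rolls up, is identity at rank, and conserves totals", {
  tax <- ladderTaxonomy()
  # strain count rolls up to its species
  expect_equal(projectToRank(c(`5` = 7), tax, "species"), c(`4` = 7))
  # counts already at rank H are untouched
  expect_equal(projectToRank(c(`4` = 3), tax, "species"), c(`4` = 3))
  # reads above a dead end go to UNRESOLVED
  noSpecies <- newTaxonomy(c(1L, 2L), c(1L, 1L), c("root", "genus"))
  out <- projectToRank(c(`2` = 4), noSpecies, "species")
  expect_equal(out[[UNRESOLVED]], 4)
})

test_that("projection conserves integer totals on random configurations", {
  set.seed(31)
  for (rep in 1:60) {
    tax <- randomTaxonomy(sample(5:80, 1L))
    populated <- sample(tax@ids, sample(1:10, 1L), replace = TRUE)
    counts <- table(populated)
    counts <- stats::setNames(as.numeric(counts), names(counts))
    rank <- sample(c("phylum", "family", "genus", "species"), 1L)
    out <- projectToRank(counts, tax, rank)
    expect_equal(sum(out), sum(counts))
    atRank <- setdiff(names(out), c(UNRESOLVED, UNASSIGNED))
    if (length(atRank)) {
      expect_true(all(taxRank(tax, as.integer(atRank)) == rank))
    }
  }
})

test_that("functional binning takes the first resolvable best hit", {
  ct <- loadHierarchy(withr::local_tempfile(lines = c(
    "sys1\tROOT\tSubsystem 1", "roleA\tsys1\tRole A",
    "roleB\tsys1\tRole B")))
  m <- newRefClassMap("id", table = c(refA = "roleA", refB = "roleB"))
  # only the 3rd-best record resolves
  aln <- rbind(alnRow("r1", "unknown1", 100), alnRow("r1", "unknown2", 90),
               alnRow("r1", "refA", 80))
  expect_equal(functionalBin(aln, m, ct)$class_id, "roleA")
  # tie on bitscore: earlier record wins
  tie <- rbind(alnRow("r2", "refB", 90), alnRow("r2", "refA", 90))
  expect_equal(functionalBin(tie, m, ct)$class_id, "roleB")
  none <- alnRow("r3", "unknown", 70)
  expect_equal(functionalBin(none, m, ct)$class_id, UNASSIGNED)
})

test_that("end-to-end genus recovery and weighted specificity on decoy samples", {
  w <- makeWorld(2, 2, 2, 3, 300, seed = 7)
  tax <- worldTaxonomy(w)
  map <- worldTaxMap(w)
  ab <- stats::setNames(rep(c(9, 1), 4), names(worldGenomes(w)))
  sim <- simulateReads(w, 400, 100, 0.02, seed = 11, abundance = ab)
  aln <- emitAlignments(w, sim, "same-genus")
  filt <- filterSignificant(aln)
  truth <- stats::setNames(sim$truth$taxon_id, sim$truth$read_id)
  naive <- naiveLCA(filt, tax, map)
  weighted <- weightedLCA(filt, computeRefWeights(filt, tax, map), tax, map)

  # most reads project to their true genus
  prof <- projectToRank(countAssignments(naive), tax, "genus")
  trueGenus <- table(vapply(truth, function(t)
    as.character(ancestorAtRank(tax, t, "genus")), ""))
  common <- intersect(names(prof), names(trueGenus))
  recovered <- sum(pmin(prof[common], trueGenus[common])) / sum(trueGenus)
  expect_gt(recovered, 0.9)

  # weighted LCA assigns at least as many reads to their true species
  speciesAcc <- function(a) mean(a$class_id == as.character(truth[a$read_id]))
  expect_gte(speciesAcc(weighted), speciesAcc(naive))
})

test_that("binSample conserves reads across bins including UNASSIGNED", {
  w <- makeWorld(1, 2, 2, 2, 300, seed = 5)
  sim <- simulateReads(w, 200, 100, 0.01, seed = 6)
  aln <- emitAlignments(w, sim, "same-genus")
  for (alg in c("naive", "weighted")) {
    prof <- binSample(aln, worldTaxonomy(w), worldTaxMap(w),
                      sampleName = "s", algorithm = alg,
                      totalReads = 200L)
    expect_s4_class(prof, "SampleProfile")
    expect_equal(sum(prof@counts), 200)
    expect_equal(prof@parameters$algorithm, alg)
  }
})
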