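tilingFixture <- function(geneLen = 600L, step = 50L, readLen = 100L,
                          seed = 3L) {
  w <- makeWorld(1, 1, 1, 1, geneLen, seed = seed)
  gene <- worldGenomes(w)[["1000"]][["gene_1"]]
  starts <- seq(1L, geneLen - readLen + 1L, by = step)
  reads <- stats::setNames(substring(gene, starts, starts + readLen - 1L),
                           sprintf("read_%05d", seq_along(starts)))
  sim <- list(reads = reads,
              truth = data.frame(read_id = names(reads), taxon_id = 1000L,
                                 gene = "gene_1", pos = starts,
                                 strand = "+", n_errors = 0L))
  list(world = w, gene = gene, sim = sim,
       aln = emitAlignments(w, sim, "none"))
}

test_that("anchoring picks the best hit and normalizes orientation", {
  fx <- tilingFixture()
  tax <- worldTaxonomy(fx$world)
  anch <- anchorReads(fx$sim$reads, fx$aln, worldTaxMap(fx$world),
                      "1000", tax = tax)
  expect_equal(nrow(anch), length(fx$sim$reads))
  expect_equal(anch$dna[1L], unname(fx$sim$reads[1L]))  # forward unchanged
  # reverse read: sequence reverse-complemented, ref coords preserved
  w <- fx$world
  sim2 <- simulateReads(w, 40, 100, 0, seed = 8)
  aln2 <- emitAlignments(w, sim2, "none")
  anch2 <- anchorReads(sim2$reads, aln2, worldTaxMap(w), "1000", tax = tax)
  rev <- sim2$truth$strand == "-"
  expect_true(any(rev))
  gene <- fx$gene
  for (i in which(rev)[1:5]) {
    rid <- sim2$truth$read_id[i]
    expect_equal(anch2$dna[anch2$read_id == rid],
                 substr(gene, sim2$truth$pos[i], sim2$truth$pos[i] + 99L))
  }
})

test_that("anchoring tie-breaks equal bitscores by smaller ref id", {
  m <- newRefClassMap("id", table = c(refA = "X", refB = "X"))
  aln <- rbind(alnRow("r1", "refB", 90), alnRow("r1", "refA", 90))
  anch <- anchorReads(c(r1 = strrep("ACGT", 25)), aln, m, "X")
  expect_equal(anch$ref_id, "refA")
  # reads with no qualifying alignment are skipped and tallied
  anch2 <- anchorReads(c(r1 = strrep("ACGT", 25)), aln, m, "Y")
  expect_equal(nrow(anch2), 0L)
  expect_equal(attr(anch2, "skippedReads"), 1L)
})

test_that("overlap inference verifies implied overlaps by base comparison", {
  fx <- tilingFixture()
  anch <- anchorReads(fx$sim$reads, fx$aln, worldTaxMap(fx$world),
                      "1000", tax = worldTaxonomy(fx$world))
  g <- inferOverlaps(anch, minOverlap = 20L)
  # adjacent reads overlap by 50 nt at identity 1 with the true shift
  adj <- g@edges[g@edges$u == "read_00001" & g@edges$v == "read_00002", ]
  expect_equal(adj$overlap_len, 50)
  expect_equal(adj$identity, 1)
  expect_equal(adj$shift, 50)
  # mismatches below the identity gate suppress the edge
  s1 <- anch$dna[1L]
  bad <- anch[1:2, ]
  mutated <- strsplit(anch$dna[2L], "")[[1L]]
  mutated[1:5] <- ifelse(mutated[1:5] == "A", "C", "A")  # 5 mismatches in overlap
  bad$dna[2L] <- paste(mutated, collapse = "")
  g2 <- inferOverlaps(bad, minOverlap = 20L, minIdentity = 0.98)
  expect_equal(nrow(g2@edges), 0L)
  # reads on different references are never compared
  twoRef <- anch[1:2, ]
  twoRef$ref_id[2L] <- "other"
  expect_equal(nrow(inferOverlaps(twoRef)@edges), 0L)
})

test_that("an error-free tiling assembles into the exact gene", {
  fx <- tilingFixture()
  contigs <- assembleClass(fx$sim$reads, fx$aln, worldTaxMap(fx$world),
                           "1000", tax = worldTaxonomy(fx$world))
  expect_length(contigs, 1L)
  expect_identical(contigs[[1L]]@consensus, fx$gene)
  expect_equal(nrow(contigs[[1L]]@members), 11L)
  expect_equal(length(contigs[[1L]]@coverage), 600L)
  # soundness: members re-align to the consensus perfectly
  anch <- anchorReads(fx$sim$reads, fx$aln, worldTaxMap(fx$world),
                      "1000", tax = worldTaxonomy(fx$world))
  ident <- contigMemberIdentity(contigs[[1L]],
                                stats::setNames(anch$dna, anch$read_id))
  expect_true(all(ident == 1))
})

test_that("assembly is deterministic and respects minLength", {
  fx <- tilingFixture()
  args <- list(fx$sim$reads, fx$aln, worldTaxMap(fx$world), "1000",
               tax = worldTaxonomy(fx$world))
  c1 <- do.call(assembleClass, args)
  c2 <- do.call(assembleClass, args)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeContigsFasta(c1, f1); writeContigsFasta(c2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_length(do.call(assembleClass, c(args, minLength = 601L)), 0L)
  # empty graph -> empty list
  empty <- inferOverlaps(anchorReads(character(0), fx$aln[0, ],
                                     worldTaxMap(fx$world), "1000"))
  expect_length(extractContigs(empty), 0L)
})

test_that("strain haplotypes assemble into separate, pure contigs", {
  w <- makeWorld(1, 1, 2, 1, 600, seed = 9, speciesDivergence = 0.10)
  sim <- simulateReads(w, 150, 100, 0, seed = 5)
  aln <- filterSignificant(emitAlignments(w, sim, "same-genus"))
  contigs <- assembleClass(sim$reads, aln, worldTaxMap(w), "100",
                           tax = worldTaxonomy(w))
  expect_gte(length(contigs), 2L)
  truthTax <- stats::setNames(sim$truth$taxon_id, sim$truth$read_id)
  for (ct in contigs) {
    expect_length(unique(truthTax[ct@members$read_id]), 1L)
  }
})

test_that("contig FASTA headers carry length, read count and coverage", {
  fx <- tilingFixture()
  contigs <- assembleClass(fx$sim$reads, fx$aln, worldTaxMap(fx$world),
                           "1000", tax = worldTaxonomy(fx$world))
  f <- withr::local_tempfile()
  writeContigsFasta(contigs, f)
  hdr <- readLines(f, n = 1L)
  expect_match(hdr, "^>contig_1 len=600 reads=11 cov=1\\.83$")
})
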