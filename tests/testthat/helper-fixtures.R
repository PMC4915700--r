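# shared fixtures and independent oracles

# 5-node ladder: root -> phylum -> genus -> species -> strain
ladderTaxonomy <- function() {
  newTaxonomy(ids = c(1L, 2L, 3L, 4L, 5L),
              parent = c(1L, 1L, 2L, 3L, 4L),
              rank = c("root", "phylum", "genus", "species", "strain"),
              name = c("Root", "P", "G", "S", "St"))
}

# root -> (A -> {a1, a2}, B -> {b1}); A,B genera, leaves species
forkTaxonomy <- function() {
  newTaxonomy(ids = c(1L, 10L, 20L, 11L, 12L, 21L),
              parent = c(1L, 1L, 1L, 10L, 10L, 20L),
              rank = c("root", "genus", "genus", "species", "species",
                       "species"),
              name = c("Root", "A", "B", "a1", "a2", "b1"))
}

# random rooted taxonomy with <= n nodes; each non-root parent drawn
# uniformly among earlier nodes, ranks drawn loosely consistent
randomTaxonomy <- function(n) {
  ids <- seq_len(n)
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  major <- setdiff(taxRanks(), "norank")
  rank <- c("root", character(n - 1L))
  for (i in 2:n) {
    # strictly deeper than the nearest major-ranked ancestor, or norank
    j <- parent[i]
    while (rank[j] == "norank") j <- parent[j]
    m <- match(rank[j], major)
    allowed <- c("norank",
                 if (m < length(major)) major[(m + 1L):length(major)])
    rank[i] <- sample(allowed, 1L)
  }
  newTaxonomy(ids, parent, rank)
}

# brute-force LCA: intersect full root paths, take the deepest element
lcaOracle <- function(tax, ids) {
  paths <- lapply(ids, function(i) taxPath(tax, i))
  common <- Reduce(intersect, paths)
  common[which.max(taxDepth(tax, common))]
}

# alignment row builder (already-parsed layout)
alnRow <- function(read, ref, bits, pid = 100, len = 30, qs = 1, qe = 90,
                   ss = 1, se = 30, evalue = 1e-20, reverse = FALSE) {
  data.frame(read_id = read, ref_id = ref, pident = pid, length = len,
             mismatch = 0L, gapopen = 0L, read_start = qs, read_end = qe,
             ref_start = ss, ref_end = se, evalue = evalue,
             bitscore = bits, reverse = reverse, stringsAsFactors = FALSE)
}

profileOf <- function(name, counts, classification = "Taxonomy") {
  new("SampleProfile", sampleName = name,
      classificationName = classification, counts = counts,
      totalReads = as.integer(round(sum(counts))), parameters = list())
}

# minimal InterPro2GO input set exercising every placement rule:
#  - IPRA: one slim per domain in all 3 domains -> 3 placements
#  - IPRB: two slims in one domain -> Other
#  - IPRC: no GO annotation -> Unclassified
#  - IPRD: annotation whose term has no slim ancestor -> Unclassified
interproFixture <- function() {
  list(
    familyToGo = list(IPRA = c("GO:0000001", "GO:0000002", "GO:0000003"),
                      IPRB = c("GO:0000004", "GO:0000005"),
                      IPRD = "GO:0000099"),
    goslimTerms = data.frame(
      go_id = c("GO:0000010", "GO:0000011", "GO:0000012", "GO:0000013"),
      label = c("slim bp", "slim cc", "slim mf", "slim bp 2"),
      domain = c("biological process", "cellular component",
                 "molecular function", "biological process"),
      stringsAsFactors = FALSE),
    goAncestry = list("GO:0000001" = "GO:0000010",
                      "GO:0000002" = "GO:0000011",
                      "GO:0000003" = "GO:0000012",
                      "GO:0000004" = "GO:0000010",
                      "GO:0000005" = "GO:0000013",
                      "GO:0000099" = character(0)),
    familyLabels = c(IPRA = "family A", IPRB = "family B",
                     IPRC = "family C", IPRD = "family D"))
}

buildFixtureTree <- function() {
  fx <- interproFixture()
  buildInterpro2GO(fx$familyToGo, fx$goslimTerms, fx$goAncestry,
                   fx$familyLabels)
}
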