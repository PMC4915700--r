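#' @importFrom Biostrings translate BStringSet writeXStringSet readDNAStringSet
NULL

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

.BASES <- c("A", "C", "G", "T")

.randomGene <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

# per-site substitution at the given rate; substituted sites always
# change to one of the three other bases
.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

.translateDNA <- function(seq) {
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAStringSet(seq),
                          if.fuzzy.codon = "X", no.init.codon = TRUE)))
}

#' Generate a fully labeled synthetic metagenome world
#'
#' Builds a balanced toy taxonomy (root, phyla, genera, species) and a
#' set of protein-coding gene sequences with a controlled divergence
#' structure: each phylum carries ancestral genes, each genus derives
#' its ancestor genes from the phylum's by per-site substitution at
#' `genusDivergence` (default 0.20), and each species derives its genes
#' from the genus ancestor at `speciesDivergence` (default 0.05) --
#' roughly the identity structure of congeneric bacterial genomes. The
#' first child at each level inherits its ancestor's genes unchanged,
#' so the stated rates are pairwise divergences between siblings.
#' One reference protein per species gene is produced by translation.
#' The result is a pure function of the parameters and seed.
#'
#' @param nPhyla,nGeneraPerPhylum,nSpeciesPerGenus taxonomy shape.
#' @param genesPerSpecies number of genes per species genome.
#' @param geneLen gene length in nt, divisible by 3.
#' @param seed RNG seed.
#' @param speciesDivergence,genusDivergence per-site substitution rates
#'   between species within a genus and between genus ancestors within
#'   a phylum.
#' @return A [SyntheticWorld].
#' @export
#' @examples
#' w <- makeWorld(1, 1, 2, 1, 300, seed = 7)
#' taxSize(worldTaxonomy(w))
makeWorld <- function(nPhyla = 2L, nGeneraPerPhylum = 2L,
                      nSpeciesPerGenus = 2L, genesPerSpecies = 3L,
                      geneLen = 300L, seed = 1L,
                      speciesDivergence = 0.05, genusDivergence = 0.20) {
  if (nPhyla < 1L || nGeneraPerPhylum < 1L || nSpeciesPerGenus < 1L ||
      genesPerSpecies < 1L || geneLen < 3L) {
    stop("world dimensions must be positive")
  }
  if (geneLen %% 3L != 0L) stop("geneLen must be divisible by 3")
  .withSeed(seed, {
    ids <- 1L; parent <- 1L; rank <- "root"; name <- "Root"
    genomes <- list()
    refs <- list()
    speciesCounter <- 0L
    for (p in seq_len(nPhyla)) {
      pid <- 10L + p - 1L
      ids <- c(ids, pid); parent <- c(parent, 1L)
      rank <- c(rank, "phylum"); name <- c(name, sprintf("Phylum_%d", p))
      phylumGenes <- vapply(seq_len(genesPerSpecies),
                            function(g) .randomGene(geneLen), "")
      for (g in seq_len(nGeneraPerPhylum)) {
        gid <- 100L + (p - 1L) * nGeneraPerPhylum + g - 1L
        ids <- c(ids, gid); parent <- c(parent, pid)
        rank <- c(rank, "genus")
        name <- c(name, sprintf("Genus_%d_%d", p, g))
        # the first genus inherits the phylum ancestor unchanged, so
        # the stated rate is the pairwise divergence to its siblings
        genusGenes <- if (g == 1L) phylumGenes else
          vapply(phylumGenes, .mutate, "", rate = genusDivergence)
        for (s in seq_len(nSpeciesPerGenus)) {
          speciesCounter <- speciesCounter + 1L
          sid <- 1000L + speciesCounter - 1L
          ids <- c(ids, sid); parent <- c(parent, gid)
          rank <- c(rank, "species")
          name <- c(name, sprintf("Species_%d_%d_%d", p, g, s))
          genes <- if (s == 1L) genusGenes else
            vapply(genusGenes, .mutate, "", rate = speciesDivergence)
          names(genes) <- sprintf("gene_%d", seq_len(genesPerSpecies))
          genomes[[as.character(sid)]] <- genes
          for (k in seq_len(genesPerSpecies)) {
            refs[[length(refs) + 1L]] <- data.frame(
              ref_id = sprintf("g%d|tax|%d|%s", k, sid,
                               sprintf("Species_%d_%d_%d", p, g, s)),
              protein = .translateDNA(genes[[k]]),
              taxon_id = sid, class_id = sprintf("F%d", k),
              gene = sprintf("gene_%d", k), stringsAsFactors = FALSE)
          }
        }
      }
    }
    new("SyntheticWorld",
        taxonomy = newTaxonomy(ids, parent, rank, name),
        genomes = genomes,
        references = do.call(rbind, refs),
        params = list(nPhyla = nPhyla,
                      nGeneraPerPhylum = nGeneraPerPhylum,
                      nSpeciesPerGenus = nSpeciesPerGenus,
                      genesPerSpecies = genesPerSpecies,
                      geneLen = geneLen, seed = seed,
                      speciesDivergence = speciesDivergence,
                      genusDivergence = genusDivergence))
  })
}

#' SyntheticWorld accessors
#' @param world a [SyntheticWorld].
#' @return `worldTaxonomy`: the toy [Taxonomy]; `worldReferences`: the
#'   reference data.frame; `worldGenomes`: the per-species gene list.
#' @export
worldTaxonomy <- function(world) world@taxonomy

#' @rdname worldTaxonomy
#' @export
worldReferences <- function(world) world@references

#' @rdname worldTaxonomy
#' @export
worldGenomes <- function(world) world@genomes

#' Taxonomic reference map for a synthetic world
#'
#' Reference ids embed the taxon as a `tax|<id>` header tag, so the
#' taxonomic map is simply tag resolution; the functional map is a
#' token table from reference id to the gene's functional class.
#'
#' @param world a [SyntheticWorld].
#' @return A [RefClassMap].
#' @export
worldTaxMap <- function(world) newRefClassMap("tag", tag = "tax")

#' @rdname worldTaxMap
#' @export
worldFunctionalMap <- function(world) {
  newRefClassMap("id", table = stats::setNames(world@references$class_id,
                                               world@references$ref_id))
}

#' Simulate shotgun reads from a synthetic world
#'
#' Uniform sampling of species (or a supplied abundance weighting),
#' gene and start position; strand chosen uniformly; per-base
#' substitution errors at `errorRate`. With `errorRate = 0` every read
#' is an exact (possibly reverse-complemented) genome substring. A
#' truth table records each read's origin.
#'
#' @param world a [SyntheticWorld].
#' @param nReads number of reads.
#' @param readLen read length in nt (at most `geneLen`).
#' @param errorRate per-base substitution probability.
#' @param seed RNG seed.
#' @param abundance optional named weights by species taxon id.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame `read_id, taxon_id, gene, pos, strand, n_errors`).
#' @export
simulateReads <- function(world, nReads = 1000L, readLen = 100L,
                          errorRate = 0, seed = 1L, abundance = NULL) {
  geneLen <- world@params$geneLen
  if (readLen > geneLen) stop("readLen exceeds geneLen")
  speciesIds <- names(world@genomes)
  wts <- if (is.null(abundance)) {
    rep(1, length(speciesIds))
  } else {
    as.numeric(abundance[speciesIds])
  }
  .withSeed(seed, {
    sp <- sample(speciesIds, nReads, replace = TRUE, prob = wts)
    gene <- sample(names(world@genomes[[1L]]), nReads, replace = TRUE)
    pos <- sample.int(geneLen - readLen + 1L, nReads, replace = TRUE)
    strand <- sample(c("+", "-"), nReads, replace = TRUE)
    reads <- character(nReads)
    nerr <- integer(nReads)
    for (i in seq_len(nReads)) {
      s <- substr(world@genomes[[sp[i]]][[gene[i]]], pos[i],
                  pos[i] + readLen - 1L)
      if (errorRate > 0) {
        before <- s
        s <- .mutate(s, errorRate)
        nerr[i] <- sum(utf8ToInt(before) != utf8ToInt(s))
      }
      if (strand[i] == "-") s <- .revcomp(s)
      reads[i] <- s
    }
    ids <- sprintf("read_%05d", seq_len(nReads))
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, taxon_id = as.integer(sp),
                            gene = gene, pos = pos, strand = strand,
                            n_errors = nerr, stringsAsFactors = FALSE))
  })
}

# amino-acid interval of the gene codons fully covered by nt [s, e]
.codonSpan <- function(s, e) {
  c(as.integer(ceiling((s + 2L) / 3L)), as.integer(e %/% 3L))
}

#' Emit oracle protein alignments for simulated reads
#'
#' Writes the tabular alignment rows a translated aligner would produce
#' for each read, computed by exact codon comparison at the known
#' sampling offset rather than by heuristic search: each read is
#' compared against its true reference and, per `decoyPolicy`, against
#' the homologous gene of the other species of the same genus
#' (`"same-genus"`) or of the whole phylum (`"same-phylum"`). Scores
#' use match = +2, mismatch = -1 on aligned amino acids. Reverse-strand
#' reads get swapped read coordinates, as a translated aligner reports
#' them.
#'
#' @param world a [SyntheticWorld].
#' @param sim result of [simulateReads()].
#' @param decoyPolicy `"none"`, `"same-genus"` or `"same-phylum"`.
#' @return Alignment data.frame in the normalized layout of
#'   [readBlastTab()], read-contiguous, each read's rows in descending
#'   bitscore order. Serialize with [writeBlastTab()].
#' @export
emitAlignments <- function(world, sim,
                           decoyPolicy = c("same-genus", "none",
                                           "same-phylum")) {
  decoyPolicy <- match.arg(decoyPolicy)
  tax <- world@taxonomy
  refs <- world@references
  rows <- vector("list", nrow(sim$truth) * 2L)
  nrow_ <- 0L
  readLen <- nchar(sim$reads[[1L]])
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    span <- .codonSpan(tr$pos, tr$pos + readLen - 1L)
    if (span[2L] < span[1L]) next
    # gene-forward version of the read, translated over covered codons
    fwd <- if (tr$strand == "-") .revcomp(sim$reads[[tr$read_id]]) else
      sim$reads[[tr$read_id]]
    qs <- (3L * span[1L] - 2L) - tr$pos + 1L
    qe <- 3L * span[2L] - tr$pos + 1L
    readAA <- .translateDNA(substr(fwd, qs, qe))
    candidates <- switch(decoyPolicy,
      "none" = tr$taxon_id,
      "same-genus" = {
        g <- taxParent(tax, tr$taxon_id)
        sort(taxChildren(tax, g))
      },
      "same-phylum" = {
        ph <- ancestorAtRank(tax, tr$taxon_id, "phylum")
        unlist(lapply(sort(taxChildren(tax, ph)),
                      function(g) sort(taxChildren(tax, g))))
      })
    recs <- list()
    for (sid in candidates) {
      ref <- refs[refs$taxon_id == sid & refs$gene == tr$gene, ]
      refAA <- substr(ref$protein, span[1L], span[2L])
      m <- .baseMatches(readAA, refAA)
      if (m == 0L) next
      len <- span[2L] - span[1L] + 1L
      score <- 2L * m - (len - m)
      if (score <= 0L) next
      q1 <- qs; q2 <- qe
      if (tr$strand == "-") {
        q1 <- readLen - qs + 1L
        q2 <- readLen - qe + 1L
      }
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = tr$read_id, ref_id = ref$ref_id,
        pident = round(100 * m / len, 1L), length = len,
        mismatch = len - m, gapopen = 0L,
        read_start = min(q1, q2), read_end = max(q1, q2),
        ref_start = span[1L], ref_end = span[2L],
        evalue = signif(2^(-score), 3L), bitscore = score,
        reverse = tr$strand == "-", stringsAsFactors = FALSE)
    }
    if (!length(recs)) next
    recs <- do.call(rbind, recs)
    recs <- recs[order(-recs$bitscore, recs$ref_id), , drop = FALSE]
    nrow_ <- nrow_ + 1L
    rows[[nrow_]] <- recs
  }
  if (!nrow_) return(parseBlastTab(character(0)))
  out <- do.call(rbind, rows[seq_len(nrow_)])
  rownames(out) <- NULL
  out
}

#' Write simulated reads as FASTQ (constant quality)
#'
#' @param reads named character vector of read sequences.
#' @param file output path.
#' @param quality constant per-base Phred+33 quality character.
#' @return `file`, invisibly.
#' @export
writeReadsFastq <- function(reads, file, quality = "I") {
  lines <- as.vector(rbind(paste0("@", names(reads)),
                           unname(reads),
                           "+",
                           strrep(quality, nchar(reads))))
  writeLines(lines, file)
  invisible(file)
}

#' Read a FASTQ or FASTA file into a named character vector
#'
#' @param file path; format detected from the first character.
#' @return Named character vector of sequences.
#' @export
readSequences <- function(file) {
  first <- substr(readLines(file, n = 1L), 1L, 1L)
  fmt <- if (first == "@") "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(file, format = fmt)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write all synthetic-world fixture files to a directory
#'
#' Emits the taxonomy TSV, reference protein FASTA, functional mapping
#' TSV and ground-truth gene FASTA so that file-based entry points can
#' be exercised end to end.
#'
#' @param world a [SyntheticWorld].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeWorldFiles <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(taxonomy = file.path(dir, "taxonomy.tsv"),
             references = file.path(dir, "references.faa"),
             funmap = file.path(dir, "fun-map.tsv"),
             genes = file.path(dir, "genes.fna"))
  writeTaxonomy(world@taxonomy, paths[["taxonomy"]])
  writeLines(as.vector(rbind(paste0(">", world@references$ref_id),
                             world@references$protein)),
             paths[["references"]])
  utils::write.table(world@references[, c("ref_id", "class_id")],
                     paths[["funmap"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  genes <- unlist(lapply(names(world@genomes), function(sid) {
    g <- world@genomes[[sid]]
    stats::setNames(unname(g), paste0("tax", sid, "_", names(g)))
  }))
  writeLines(as.vector(rbind(paste0(">", names(genes)), unname(genes))),
             paths[["genes"]])
  invisible(paths)
}

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(paste0("SyntheticWorld: %d taxa, %d species genomes, ",
                     "%d reference proteins (seed %d)\n"),
              taxSize(object@taxonomy), length(object@genomes),
              nrow(object@references), object@params$seed))
})
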