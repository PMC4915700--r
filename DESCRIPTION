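Package: lcabin
Title: Taxonomic and Functional Binning of Metagenomic Protein Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch analysis of shotgun metagenome samples from tabular
    DNA-to-protein alignments. Implements naive and weighted
    lowest-common-ancestor (LCA) taxonomic binning against an NCBI-style
    taxonomy, projection of across-rank assignments onto fixed-rank
    profiles, construction of functional classification trees (including
    an InterPro-to-GO-slim tree), multi-sample comparison with metadata
    (total and core biome, attribute grouping), ecological distances and
    principal coordinate analysis with bi-plot and tri-plot vectors,
    alpha diversity indices, and gene-centric assembly of reads guided by
    their protein alignments. A synthetic-world generator produces fully
    labeled toy taxonomies, reference proteins, reads and alignment
    tables so that every component can be exercised without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
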