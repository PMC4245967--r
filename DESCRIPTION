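Package: pansynt
Title: Pairwise Bacterial Synteny Blocks, Orthology and Pangenome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational back end for pairwise comparative genomics of
    bacteria and archaea. Reads annotated complete genomes (GenBank, EMBL or
    GFF3 with protein FASTA), filters all-vs-all protein hit tables, calls
    orthologs by bidirectional best hit, detects collinear and inverted
    synteny blocks by local dynamic programming over gene orders with an
    affine gap model, segments each comparison into a chain of annotation
    events (conserved blocks and genome-specific regions), builds gene-by-
    genome presence/absence profiles with a combinable filter algebra and
    core/dispensable set construction, compares functional annotations of a
    gene against its homologs (shared/missing/unique), computes binomial
    enrichment statistics for gene-set/locus overlap, renders a static SVG of
    a comparison, and ships a seeded simulator of genome pairs with planted
    rearrangements and matching hit tables for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    Biostrings,
    xml2
Config/testthat/edition: 3
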