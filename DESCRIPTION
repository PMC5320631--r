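Package: regulogR
Title: Comparative-Genomics Reconstruction of Bacterial Transcription-Factor Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs bacterial transcription-factor regulons by
    comparative genomics. Implements phylogenetic footprinting with
    repeat-aware (direct/inverted dyad) motif discovery over upstream
    regions of orthologous genes, position weight matrix construction and
    both-strand scanning with a training-set derived score threshold and a
    weak-site rescue rule, operon prediction from intergenic distances,
    cross-genome consistency-check regulon assembly into regulogs, and
    classification of operator motifs into box-arrangement categories
    (direct and inverted repeats of two to four boxes). A synthetic-genome
    generator plants operator sites, operons and ortholog families with a
    full ground-truth manifest so every stage of the pipeline can be
    exercised and benchmarked without external data. Bundles summary
    tables from a large-scale reconstruction of MocR-subfamily regulons
    for the reporting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
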