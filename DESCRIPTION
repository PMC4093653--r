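Package: beanTE
Title: Transposable-Element Annotation Toolkit with a Truth-Tracked Synthetic Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo and homology-guided annotation of transposable elements
    in small plant genome assemblies, modelled on the annotation workflow used
    for the common bean (Phaseolus vulgaris) transposon database. Provides
    structural discovery of LTR retrotransposons (paired long terminal
    repeats, TG...CA termini, target-site duplications), six-frame translated
    homology search against conserved transposase and reverse-transcriptase
    domains with 10-kb flank extraction, superfamily classification by
    terminal motifs, terminal inverted repeats, TSD lengths and polyA tails,
    single-linkage family clustering into a representative library, EST-based
    expression summaries, detection of envelope-like and antisense ORF2 extra
    open reading frames in LTR-element internal regions, and neighbor-joining
    phylogenetics of reverse-transcriptase domains. A truth-tracked
    synthetic-genome generator plants elements of every supported superfamily
    so the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    data.table,
    igraph,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
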