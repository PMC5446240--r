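Package: pho4cycle
Title: Mutant-Cycle Analysis of Transcription Factor and Co-Activator
    Control of Gene Induction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting how a transcription factor's dependence on
    a co-activator shapes its target gene set, modeled on the yeast
    phosphate-starvation (PHO) system. Implements threshold fold-change
    differential-induction testing on factorial genotype designs
    (TMM-normalized log2-CPM, empirical-Bayes moderated variances, TREAT
    composite-null tests, globally pooled FDR), double-mutant-cycle
    decomposition of induction into TF-alone, cofactor-alone and
    collaborative components with Ward clustering into expression classes,
    ChIP coverage-track normalization and peak calling with cofactor
    co-binding and dependence classification, E-box (CACGTG) motif scanning
    with mismatch grading, and peak-to-promoter target assignment joined to
    induction calls. Ships seeded synthetic-data generators (toy genomes,
    negative-binomial factorial count matrices, Gaussian-bump ChIP tracks)
    with machine-readable planted truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
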