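Package: dollotrace
Title: Synteny-Anchored Orthology, Pseudogene Lesions and Dollo Parsimony
    Reconstruction of Keratin Gene Loss
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative-genomics toolkit for tracing the gain and loss of
    genes in a conserved gene cluster across species. Provides
    synteny-anchored positional ortholog calling from per-species gene maps,
    detection of inactivating lesions (premature stop codons, frameshift
    indels) in coding sequences with a nonsense-mediated decay rule, Dollo
    and Sankoff maximum-parsimony reconstruction of gain/loss events on a
    timed species tree with branch-interval dating, loss-pattern
    co-evolution statistics with a permutation null, putative type I:type II
    keratin heterodimer inference, and qPCR relative quantification under
    the amplification-efficiency model with an exact Mann-Whitney U test.
    Includes a synthetic-data generator with known ground truth and packaged
    fixtures describing the keratin KRT24 locus in tetrapods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
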