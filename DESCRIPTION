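Package: nifhdiv
Title: Frame-Aware Denoising, Clustering and Diversity Analysis of nifH
    Amplicon Pyrosequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for functional-gene (nifH) amplicon surveys
    sequenced on homopolymer-error-prone platforms. Implements read-level
    quality control with frame-aware denoising (primer trimming, length and
    ambiguity filters, clipping, translation, in-frame stop rejection, and a
    position-specific profile alignment filter for frameshifted reads),
    screening against reagent-contaminant reference sequences, exact
    complete-linkage clustering of amino-acid sequences at multiple identity
    thresholds, depth normalization by random subsampling with rarefaction,
    Chao1 and Shannon diversity, and between-sample comparison via the
    Sorensen index, neighbor-joining phylogenies, weighted UniFrac distances
    and principal coordinates analysis. A synthetic-read generator with full
    ground truth (variant pools with designed cluster structure, 454-style
    homopolymer indels, substitutions, ambiguous bases, short reads and
    contaminant spike-ins) makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    phyloseq,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
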