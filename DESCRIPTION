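Package: soluprof
Title: Categorical Analysis of Protein Amenability to Soluble Cell-Free Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying physicochemical, structural, motif and
    post-translational-modification-site properties of amino-acid sequences
    associated with soluble cell-free expression. Implements categorical
    A/C/N scoring of expression outcomes (soluble, insoluble, non-expressed),
    ProtParam-class sequence features (composition, molecular weight, net
    charge, isoelectric point, GRAVY), a PROSITE-syntax motif scanner with a
    bundled PTM-site catalogue, sequence-computable structural features (PEST
    regions, coiled coils, baseline transmembrane and disorder profiles),
    per-category correlation profiling with Fisher's exact and one-tailed
    Pearson significance testing, and a seeded synthetic-dataset generator
    with planted feature-category effects for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
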