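Package: coiDiag
Title: Species-Diagnostic PCR Panel Design and In Silico Validation from
    COI Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building PCR assays that identify morphologically
    similar insect species by amplicon size. From aligned mitochondrial
    COI (cytochrome c oxidase subunit I) barcode sequences the package
    locates species-diagnostic substitution sites and conserved windows,
    assembles assay panels consisting of one common reverse primer and
    species-specific forward primers yielding size-separated amplicons,
    validates panels by in silico PCR under an IUPAC-aware
    mismatch-tolerance binding model, and classifies field samples from
    observed band sizes. Includes a seeded synthetic barcode generator
    for fully reproducible end-to-end testing, and a command-line
    interface wiring the design, validation and classification steps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: SequenceMatching, Alignment, SNPDiscovery
Config/testthat/edition: 3
RoxygenNote: 7.3.3
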