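Package: saavbench
Title: Benchmarking Single Amino Acid Variant Detection from Open-Search Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking mass-spectrometry search strategies in
    detecting single amino acid variations (SAAVs) such as those caused by
    translational errors. Builds a cross-species (human/mouse) SAAV ground
    truth by in silico tryptic digestion and cognate-peptide pairing, assigns
    SAAVs to open-search mass-shift PSMs by a three-criterion rule, and scores
    candidate calls at the PSM level with precision, sensitivity and F1 under
    single-tool and mixed gold standards. Includes orthogonal PSM quality
    metrics (retention-time deviation, normalized spectral angle) and a fully
    seeded synthetic-data generator that emulates patient-derived xenograft
    style mixed-species PSM populations with controlled error modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
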