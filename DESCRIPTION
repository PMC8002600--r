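Package: icmaldi
Title: Intact-Cell MALDI-TOF Profile Analysis for Microbial Biotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intact-cell MALDI-TOF mass spectrometry
    profiles of microorganisms. Builds consensus peak profiles (main spectra
    projections) from replicate peak lists, detects newly appeared and missing
    peaks between treated cultures and their controls, annotates peaks by
    theoretical protein masses computed from a proteome FASTA within a mass
    tolerance window, and clusters profiles into average-linkage dendrograms
    using correlation distance. Includes a synthetic-data generator that
    emulates dose- and time-dependent treatment effects on peak profiles so
    the whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    ape,
    Biostrings,
    yaml,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
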