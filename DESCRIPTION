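Package: fretscreen
Title: FRET-Restraint Screening of Protein-Protein Docking Poses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fluorescence resonance energy transfer (FRET)
    measurements between multiply labeled protein homodimers and for screening
    candidate docking poses of their complex against those measurements.
    Implements Forster-law forward and inverse calculations, combination rules
    for multi-fluorophore labeling schemes with occupancy weights, spectral
    unmixing of donor/acceptor absorbance and emission spectra with
    donor-quenching and stimulated-emission efficiency estimators, extraction
    of C-beta label-site coordinates from PDB coordinate files, per-pose
    predicted efficiency sets with sum-of-squares scoring and qualitative
    selection criteria, robustness resampling over unequal label occupancies,
    interface residue contact analysis with sequence-region grouping, and a
    synthetic-data generator producing toy dimer structures, pose decoy
    ensembles, noisy measured-efficiency tables and Gaussian-band spectra so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
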