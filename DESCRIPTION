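Package: SpectralAccuracy
Title: Accurate Mass and Spectral Accuracy on Low-Resolution Quadrupole Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-acquisition mass calibration of profile spectra from
    low-resolution (triple quadrupole) mass spectrometers using internal
    calibrants, exhaustive molecular-formula candidate enumeration under
    element-range, RDBE and electron-configuration constraints, theoretical
    isotope-pattern computation by elemental convolution, and spectral
    accuracy (SA) scoring and ranking of candidates against the calibrated
    profile isotope pattern. Includes a synthetic-spectrum generator that
    emulates ESI+ profile acquisitions at resolving power ~500 with
    mass-axis distortion, noise and interference peaks, plus mzML/CSV I/O
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ProtGenerics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mzR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'isotope-data.R'
    'AllGenerics.R'
    'AllClasses.R'
    'chem-core.R'
    'formula-search.R'
    'isotope-patterns.R'
    'calibration.R'
    'scoring.R'
    'spectra-io.R'
    'synth.R'
    'cli.R'
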