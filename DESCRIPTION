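Package: qNMRsynth
Title: Synthetic-Spectrum Calibration for Quantitative Low-Field NMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for calibration-free quantification of overlapping
    benchtop (low-field) 1H NMR spectra. Provides a pseudo-Voigt
    mixture model of pure-component spectra with component shifts,
    group shifts and peak broadening; generators for large synthetic
    training sets built either from altered measured pure-component
    spectra or from the parametric spectral model with empirical
    baseline noise; a compact locally-connected 1-D convolutional
    network that regresses per-component signal areas from a spectrum;
    an indirect-hard-modeling style nonlinear least-squares baseline;
    and a curation pipeline for paired analyzer time series
    (nearest-neighbour pairing, steady-state detection, outlier
    removal, Kennard-Stone subset selection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, minpack.lm, pracma
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'ann.R'
    'spectral-model.R'
    'augment.R'
    'io.R'
    'pure-fit.R'
    'reference-pipeline.R'
    'toy-library.R'
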