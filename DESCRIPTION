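Package: mwtselect
Title: Mother-Wavelet Selection and Sub-Band Analysis for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Selects, for each scalp region of a multichannel EEG recording,
    the orthogonal mother-wavelet basis whose SURE soft-threshold denoised
    output is maximally cross-correlated with the band-limited signal, and
    quantifies sub-band relative spectral power after denoising. Provides a
    45-wavelet candidate bank (Daubechies db1-db20, Symlets sym1-sym20,
    Coiflets coif1-coif5), an orthogonal filter-bank discrete wavelet
    transform with multiresolution reconstruction, conventional notch and
    band-pass preprocessing, epoching and 10-20 scalp-region grouping,
    level-dependent Stein unbiased risk (SURE) soft thresholding, one-way and
    two-way ANOVA with Duncan's multiple range post-hoc test, dyadic EEG band
    mapping with relative power computation, and a seeded synthetic EEG
    generator for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
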