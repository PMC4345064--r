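Package: ftirherb
Title: ATR-FTIR Fingerprinting and Classification of Herbal Materials
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for authenticating herbal raw materials from their
    attenuated total reflection Fourier-transform infrared (ATR-FTIR)
    absorbance fingerprints. Provides an S4 data model for spectra on a
    common wavenumber grid (built on SummarizedExperiment), CSV and
    JCAMP-DX import/export, replicate averaging, automatic baseline
    correction (rubberband and polynomial), Fourier self-deconvolution
    for band narrowing, multi-level Daubechies discrete wavelet
    decomposition with band-averaged wavelet-energy feature extraction,
    and a Parzen-window probabilistic neural network classifier, together
    with an end-to-end evaluation pipeline and a synthetic three-class
    spectrum generator for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
biocViews: Spectrometry, Classification, Preprocessing
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'baseline.R'
    'dwt.R'
    'fsd.R'
    'ftirherb-package.R'
    'io.R'
    'utils.R'
    'pnn.R'
    'pipeline.R'
    'spectrum-methods.R'
    'synthetic.R'
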