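#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Spectrum: a single absorbance trace on a wavenumber grid
#'
#' The basic data object: one ATR-FTIR absorbance spectrum sampled on a
#' strictly monotonic wavenumber grid (stored descending, e.g. 4000 ->
#' 650 cm^-1, matching instrument convention), with an optional class
#' label and free-form metadata.
#'
#' @slot wavenumbers numeric, strictly decreasing grid in cm^-1.
#' @slot absorbance numeric, same length, finite.
#' @slot label character(1), class label or \code{NA}.
#' @slot meta list of provenance key/value pairs.
#'
#' @examples
#' s <- Spectrum(c(4000, 3998, 3996), c(0.1, 0.2, 0.1), label = "classA")
#' wavenumbers(s)
#' @name Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  representation(wavenumbers = "numeric", absorbance = "numeric",
                 label = "character", meta = "list"),
  prototype(label = NA_character_, meta = list()))

setValidity("Spectrum", function(object) {
  w <- object@wavenumbers; a <- object@absorbance
  if (length(w) != length(a))
    return("wavenumbers and absorbance must have equal length")
  if (length(w) < 2L)
    return("a spectrum needs at least 2 points")
  d <- diff(w)
  if (!all(d < 0))
    return("wavenumbers must be strictly decreasing (stored 4000 -> 650)")
  if (!all(is.finite(a)))
    return("all absorbance values must be finite")
  if (length(object@label) != 1L)
    return("label must be a single character value (or NA)")
  TRUE
})

#' Create a Spectrum
#'
#' The input grid may be ascending or descending; it is normalised to
#' descending storage order.
#'
#' @param wavenumbers numeric grid in cm^-1, strictly monotonic.
#' @param absorbance numeric absorbance values, same length.
#' @param label optional class label.
#' @param meta optional list of metadata.
#' @return A \linkS4class{Spectrum}.
#' @export
Spectrum <- function(wavenumbers, absorbance, label = NA_character_,
                     meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length")
  d <- diff(wavenumbers)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("wavenumbers must be strictly monotonic")
  if (length(d) && all(d > 0)) {      # ascending input: flip
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  }
  new("Spectrum", wavenumbers = wavenumbers, absorbance = absorbance,
      label = as.character(label), meta = meta)
}

#' SpectrumSet: labelled spectra sharing one wavenumber grid
#'
#' A thin \linkS4class{SummarizedExperiment} wrapper: the single assay
#' \code{"absorbance"} holds the points-by-spectra matrix, \code{rowData}
#' carries the common wavenumber grid and \code{colData} the per-spectrum
#' class labels.
#'
#' @name SpectrumSet-class
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'absorbance' is required")
  if (!"wavenumber" %in% colnames(SummarizedExperiment::rowData(object)))
    return("rowData column 'wavenumber' is required")
  w <- SummarizedExperiment::rowData(object)$wavenumber
  if (length(w) >= 2L && !all(diff(w) < 0))
    return("shared wavenumber grid must be strictly decreasing")
  if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
    return("colData column 'label' is required")
  a <- SummarizedExperiment::assay(object, "absorbance")
  if (!all(is.finite(a)))
    return("all absorbance values must be finite")
  TRUE
})

#' Create a SpectrumSet
#'
#' Either from a list of \linkS4class{Spectrum} objects sharing an
#' identical grid, or from an absorbance matrix plus a grid.
#'
#' @param spectra list of \linkS4class{Spectrum} objects, or \code{NULL}.
#' @param absorbance points-by-spectra numeric matrix (used when
#'   \code{spectra} is \code{NULL}).
#' @param wavenumbers common grid (descending or ascending; normalised).
#' @param labels character vector of per-spectrum labels.
#' @return A \linkS4class{SpectrumSet}.
#' @export
SpectrumSet <- function(spectra = NULL, absorbance = NULL,
                        wavenumbers = NULL, labels = NULL) {
  if (!is.null(spectra)) {
    stopifnot(length(spectra) >= 1L,
              all(vapply(spectra, is, logical(1), "Spectrum")))
    w <- spectra[[1L]]@wavenumbers
    for (s in spectra)
      if (!identical(s@wavenumbers, w))
        stop("all member spectra must share an identical wavenumber grid")
    absorbance <- vapply(spectra, slot, numeric(length(w)), "absorbance")
    wavenumbers <- w
    if (is.null(labels))
      labels <- vapply(spectra, slot, character(1), "label")
  } else {
    absorbance <- as.matrix(absorbance)
    if (is.null(wavenumbers) || nrow(absorbance) != length(wavenumbers))
      stop("'wavenumbers' must match the rows of 'absorbance'")
    if (all(diff(wavenumbers) > 0)) {
      wavenumbers <- rev(wavenumbers)
      absorbance <- absorbance[rev(seq_len(nrow(absorbance))), , drop = FALSE]
    }
  }
  if (is.null(labels)) labels <- rep(NA_character_, ncol(absorbance))
  if (is.null(colnames(absorbance)))
    colnames(absorbance) <- sprintf("spec%03d", seq_len(ncol(absorbance)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = absorbance),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = S4Vectors::DataFrame(label = as.character(labels),
                                   row.names = colnames(absorbance)))
  new("SpectrumSet", se)
}

#' FSDParams: Fourier self-deconvolution parameters
#'
#' @slot enhancement narrowing factor K >= 1: the ratio by which the
#'   assumed band FWHM is reduced.
#' @slot bandwidth assumed underlying Lorentzian FWHM in cm^-1 (> 0).
#' @slot apodization smoothing window: \code{"triangular_squared"}
#'   (default), \code{"bessel"} or \code{"boxcar"}.
#' @name FSDParams-class
#' @exportClass FSDParams
setClass("FSDParams",
  representation(enhancement = "numeric", bandwidth = "numeric",
                 apodization = "character"),
  prototype(enhancement = 3.5, bandwidth = 77.0,
            apodization = "triangular_squared"))

setValidity("FSDParams", function(object) {
  if (length(object@enhancement) != 1L || object@enhancement < 1)
    return("enhancement must be a single value >= 1")
  if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
    return("bandwidth must be a single positive value (cm^-1)")
  if (!object@apodization %in% c("triangular_squared", "bessel", "boxcar"))
    return("apodization must be 'triangular_squared', 'bessel' or 'boxcar'")
  TRUE
})

#' @param enhancement narrowing factor K (default 3.5).
#' @param bandwidth assumed line FWHM in cm^-1 (default 77.0).
#' @param apodization window name.
#' @return An \code{FSDParams} object.
#' @rdname FSDParams-class
#' @export
FSDParams <- function(enhancement = 3.5, bandwidth = 77.0,
                      apodization = c("triangular_squared", "bessel",
                                      "boxcar")) {
  new("FSDParams", enhancement = enhancement, bandwidth = bandwidth,
      apodization = match.arg(apodization))
}

#' WaveletFeatureConfig: wavelet decomposition and feature settings
#'
#' @slot wavelet Daubechies family member (\code{"db2"} .. \code{"db8"}).
#' @slot levels decomposition depth (default 5).
#' @slot detailLevels detail scales feeding features (default 2:4).
#' @slot nBands contiguous feature bands per detail signal (default 3).
#' @slot bandEdges optional list, named by detail level, of explicit
#'   coefficient-index boundaries (interior cut points).
#' @slot statistic \code{"mean"} (default; average energy per band) or
#'   \code{"sum"}.
#' @name WaveletFeatureConfig-class
#' @exportClass WaveletFeatureConfig
setClass("WaveletFeatureConfig",
  representation(wavelet = "character", levels = "integer",
                 detailLevels = "integer", nBands = "integer",
                 bandEdges = "list", statistic = "character"),
  prototype(wavelet = "db4", levels = 5L, detailLevels = 2:4,
            nBands = 3L, bandEdges = list(), statistic = "mean"))

setValidity("WaveletFeatureConfig", function(object) {
  if (!object@wavelet %in% names(.dbFilters))
    return(paste("unknown wavelet; available:",
                 paste(names(.dbFilters), collapse = ", ")))
  if (object@levels < 1L) return("levels must be >= 1")
  if (any(object@detailLevels < 1L) || any(object@detailLevels > object@levels))
    return("every detail level must lie in 1..levels")
  if (object@nBands < 1L) return("nBands must be >= 1")
  if (!object@statistic %in% c("mean", "sum"))
    return("statistic must be 'mean' or 'sum'")
  TRUE
})

#' @param wavelet wavelet name (default \code{"db4"}).
#' @param levels decomposition depth.
#' @param detailLevels detail scales used for features.
#' @param nBands bands per detail signal.
#' @param bandEdges optional explicit band boundaries per level.
#' @param statistic \code{"mean"} or \code{"sum"} of squared coefficients.
#' @return A \code{WaveletFeatureConfig} object.
#' @rdname WaveletFeatureConfig-class
#' @export
WaveletFeatureConfig <- function(wavelet = "db4", levels = 5L,
                                 detailLevels = 2:4, nBands = 3L,
                                 bandEdges = list(),
                                 statistic = c("mean", "sum")) {
  new("WaveletFeatureConfig", wavelet = wavelet,
      levels = as.integer(levels),
      detailLevels = sort(as.integer(detailLevels)),
      nBands = as.integer(nBands), bandEdges = bandEdges,
      statistic = match.arg(statistic))
}

#' WaveletDecomposition: multi-level DWT coefficients
#'
#' Coefficients of a periodized orthonormal Daubechies decomposition.
#' The approximation holds the low-frequency content at the deepest
#' level; each detail holds the high-frequency content split off at that
#' level. Coefficient counts halve per level (odd lengths are padded by
#' repeating the final sample; pre-padding lengths are recorded so the
#' inverse transform is exact).
#'
#' @slot approximation numeric, approximation coefficients at depth
#'   \code{levels}.
#' @slot details list of numeric vectors, details for levels 1..levels.
#' @slot inputLengths integer, signal length entering each level
#'   (before padding).
#' @slot wavelet the wavelet used.
#' @name WaveletDecomposition-class
#' @exportClass WaveletDecomposition
setClass("WaveletDecomposition",
  representation(approximation = "numeric", details = "list",
                 inputLengths = "integer", wavelet = "character"))

#' ClassTemplate: noiseless band model of one material class
#'
#' @slot name class identifier.
#' @slot bands data.frame with columns \code{center} (cm^-1),
#'   \code{fwhm} (cm^-1, > 0), \code{amplitude} (absorbance, >= 0) and
#'   \code{shape} (\code{"lorentzian"} or \code{"gaussian"}).
#' @name ClassTemplate-class
#' @exportClass ClassTemplate
setClass("ClassTemplate",
  representation(name = "character", bands = "data.frame"))

setValidity("ClassTemplate", function(object) {
  b <- object@bands
  need <- c("center", "fwhm", "amplitude", "shape")
  if (!all(need %in% colnames(b)))
    return(paste("bands needs columns:", paste(need, collapse = ", ")))
  if (nrow(b) < 1L) return("a template needs at least one band")
  if (any(b$fwhm <= 0)) return("all band fwhm must be > 0")
  if (any(b$amplitude < 0)) return("band amplitudes must be >= 0")
  if (!all(b$shape %in% c("lorentzian", "gaussian")))
    return("band shape must be 'lorentzian' or 'gaussian'")
  TRUE
})

#' @param name class identifier.
#' @param bands band table (see slots).
#' @return A \code{ClassTemplate}.
#' @rdname ClassTemplate-class
#' @export
ClassTemplate <- function(name, bands) {
  new("ClassTemplate", name = as.character(name),
      bands = as.data.frame(bands))
}

#' NoiseModel: measurement degradation model for synthetic spectra
#'
#' @slot additiveSigma standard deviation of i.i.d. Gaussian noise added
#'   per point (absorbance units).
#' @slot baselineSlopeSigma standard deviation of the random linear
#'   baseline slope (absorbance per cm^-1).
#' @slot intensityScaleSigma standard deviation of the global
#'   multiplicative intensity jitter (unitless).
#' @slot seed integer RNG seed, or \code{NA} to use the caller's seed.
#' @name NoiseModel-class
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(additiveSigma = "numeric", baselineSlopeSigma = "numeric",
                 intensityScaleSigma = "numeric", seed = "integer"),
  prototype(additiveSigma = 0.005, baselineSlopeSigma = 2e-5,
            intensityScaleSigma = 0.01, seed = NA_integer_))

setValidity("NoiseModel", function(object) {
  if (object@additiveSigma < 0 || object@baselineSlopeSigma < 0 ||
      object@intensityScaleSigma < 0)
    return("all noise sigmas must be >= 0")
  TRUE
})

#' @param additiveSigma additive noise sd (default 0.005).
#' @param baselineSlopeSigma baseline slope sd (default 2e-5).
#' @param intensityScaleSigma intensity jitter sd (default 0.01).
#' @param seed optional RNG seed.
#' @return A \code{NoiseModel}.
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(additiveSigma = 0.005, baselineSlopeSigma = 2e-5,
                       intensityScaleSigma = 0.01, seed = NA_integer_) {
  new("NoiseModel", additiveSigma = additiveSigma,
      baselineSlopeSigma = baselineSlopeSigma,
      intensityScaleSigma = intensityScaleSigma,
      seed = as.integer(seed))
}

#' PNNModel: Parzen-window probabilistic neural network
#'
#' A PNN stores every training feature vector as a pattern-layer centre;
#' the summation layer pools a Gaussian kernel over each class's centres
#' and the output layer mixes the pooled responses through the weight
#' matrix (by default 1/n_k on the diagonal: each output unit listens
#' only to its own class).
#'
#' @slot centers n-by-p matrix of stored training vectors (standardised
#'   if \code{standardize} is \code{TRUE}).
#' @slot classIndex integer class index (1..M) of every centre.
#' @slot classNames ordered class labels.
#' @slot sigma shared Parzen kernel bandwidth (> 0).
#' @slot weights M-by-M output mixing weights w_jk.
#' @slot standardize whether features are z-scored before kernel
#'   distances.
#' @slot center,scale per-feature standardisation parameters fitted on
#'   the training data.
#' @name PNNModel-class
#' @exportClass PNNModel
setClass("PNNModel",
  representation(centers = "matrix", classIndex = "integer",
                 classNames = "character", sigma = "numeric",
                 weights = "matrix", standardize = "logical",
                 center = "numeric", scale = "numeric"))

setValidity("PNNModel", function(object) {
  if (object@sigma <= 0) return("sigma must be > 0")
  M <- length(object@classNames)
  if (M < 2L) return("a PNN needs >= 2 classes")
  if (!all(tabulate(object@classIndex, M) >= 1L))
    return("every class needs at least one centre")
  if (!all(dim(object@weights) == c(M, M)))
    return("weights must be an M-by-M matrix")
  if (nrow(object@centers) != length(object@classIndex))
    return("one classIndex entry per centre row is required")
  TRUE
})

#' PNNPrediction: classification result for one feature vector
#'
#' @slot label predicted class.
#' @slot scores per-class output values Y_j.
#' @slot posteriors scores normalised to sum 1.
#' @name PNNPrediction-class
#' @exportClass PNNPrediction
setClass("PNNPrediction",
  representation(label = "character", scores = "numeric",
                 posteriors = "numeric"))

#' PipelineConfig: settings for the end-to-end evaluation pipeline
#'
#' Binds the stage settings of the full analysis chain: baseline
#' correction, optional Fourier self-deconvolution on an analysis
#' window, wavelet-energy feature extraction and PNN classification.
#'
#' @slot baselineMethod \code{"rubberband"} or \code{"polynomial"}.
#' @slot baselineDegree degree for the polynomial method.
#' @slot fsdEnabled whether the self-deconvolution stage runs.
#' @slot fsdParams \code{\link{FSDParams}} for that stage.
#' @slot region analysis window in cm^-1, \code{c(upper, lower)};
#'   default \code{c(2000, 650)}. \code{NA} disables cropping.
#' @slot waveletConfig \code{\link{WaveletFeatureConfig}}.
#' @slot sigma fixed PNN bandwidth, or \code{NA} to select by
#'   cross-validation over \code{sigmaGrid}.
#' @slot sigmaGrid candidate bandwidths for selection.
#' @slot folds cross-validation folds for bandwidth selection.
#' @slot standardize z-score features before kernel distances.
#' @slot seed RNG seed for fold assignment.
#' @name PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(baselineMethod = "character", baselineDegree = "integer",
                 fsdEnabled = "logical", fsdParams = "FSDParams",
                 region = "numeric", waveletConfig = "WaveletFeatureConfig",
                 sigma = "numeric", sigmaGrid = "numeric", folds = "integer",
                 standardize = "logical", seed = "integer"),
  prototype(baselineMethod = "rubberband", baselineDegree = 2L,
            fsdEnabled = TRUE, region = c(2000, 650),
            sigma = NA_real_, sigmaGrid = c(0.1, 0.2, 0.5, 1, 2),
            folds = 5L, standardize = TRUE, seed = 1L))

setValidity("PipelineConfig", function(object) {
  if (!object@baselineMethod %in% c("rubberband", "polynomial"))
    return("baselineMethod must be 'rubberband' or 'polynomial'")
  if (length(object@region) != 2L)
    return("region must have length 2: c(upper, lower)")
  if (all(is.finite(object@region)) && diff(object@region) >= 0)
    return("region must be c(upper, lower) with upper > lower")
  if (object@folds < 2L) return("folds must be >= 2")
  TRUE
})

#' @param baselineMethod,baselineDegree baseline stage settings.
#' @param fsdEnabled,fsdParams self-deconvolution stage settings.
#' @param region analysis window \code{c(upper, lower)} in cm^-1.
#' @param waveletConfig feature extraction settings.
#' @param sigma,sigmaGrid,folds,standardize PNN settings.
#' @param seed RNG seed used for fold assignment.
#' @return A \code{PipelineConfig}.
#' @rdname PipelineConfig-class
#' @export
PipelineConfig <- function(baselineMethod = c("rubberband", "polynomial"),
                           baselineDegree = 2L, fsdEnabled = TRUE,
                           fsdParams = FSDParams(), region = c(2000, 650),
                           waveletConfig = WaveletFeatureConfig(),
                           sigma = NA_real_,
                           sigmaGrid = c(0.1, 0.2, 0.5, 1, 2),
                           folds = 5L, standardize = TRUE, seed = 1L) {
  new("PipelineConfig", baselineMethod = match.arg(baselineMethod),
      baselineDegree = as.integer(baselineDegree),
      fsdEnabled = fsdEnabled, fsdParams = fsdParams,
      region = as.numeric(region), waveletConfig = waveletConfig,
      sigma = as.numeric(sigma), sigmaGrid = as.numeric(sigmaGrid),
      folds = as.integer(folds), standardize = standardize,
      seed = as.integer(seed))
}

#' EvaluationReport: train/test classification results
#'
#' @slot confusion confusion matrix (rows: true class, columns:
#'   predicted class).
#' @slot perClassAccuracy named numeric, percent correct per true class.
#' @slot overallAccuracy percent correct over all test spectra.
#' @slot sigma the PNN bandwidth actually used.
#' @slot configDigest short digest identifying the pipeline settings.
#' @slot seed RNG seed of the run.
#' @name EvaluationReport-class
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(confusion = "matrix", perClassAccuracy = "numeric",
                 overallAccuracy = "numeric", sigma = "numeric",
                 configDigest = "character", seed = "integer"))
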