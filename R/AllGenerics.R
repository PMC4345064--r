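#' @include AllClasses.R
NULL

#' Wavenumber grid of a spectrum object
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{SpectrumSet}.
#' @return Numeric vector of wavenumbers in cm^-1, stored descending
#'   (4000 -> 650) following FT-IR convention.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' Absorbance values of a spectrum object
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{SpectrumSet}.
#' @return For a \code{Spectrum}, a numeric vector; for a
#'   \code{SpectrumSet}, the points-by-spectra absorbance matrix.
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' Class labels attached to spectra
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{SpectrumSet}.
#' @return Character vector of labels (\code{NA} where unlabelled).
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Automatic baseline correction
#'
#' Removes the broad background underlying an ATR-FTIR absorbance trace.
#' The default \code{"rubberband"} method subtracts the lower convex hull
#' of the spectrum (the standard vendor-style automatic baseline for
#' broadband ATR backgrounds); \code{"polynomial"} subtracts a
#' least-squares polynomial trend of the requested degree.
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{SpectrumSet}.
#' @param method \code{"rubberband"} (default) or \code{"polynomial"}.
#' @param degree polynomial degree (ignored for rubberband); must be
#'   non-negative and smaller than the number of points.
#' @return An object of the same class with the baseline subtracted.
#'   For rubberband the corrected absorbance is >= -1e-9 everywhere and
#'   the operation is idempotent.
#' @export
setGeneric("autoBaseline", function(x, method = c("rubberband", "polynomial"),
                                    degree = 2L) standardGeneric("autoBaseline"))

#' Fourier self-deconvolution
#'
#' Narrows overlapped absorption bands by dividing the assumed Lorentzian
#' lineshape out of the interferogram (Fourier) domain and re-apodizing,
#' leaving peak positions and integrated areas unchanged. See
#' \code{\link{FSDParams}} for the narrowing parameters.
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{SpectrumSet} on a
#'   uniform wavenumber grid.
#' @param params an \code{\link{FSDParams}} object.
#' @return An object of the same class on the same grid with narrowed
#'   bands. An isolated Lorentzian whose FWHM equals
#'   \code{bandwidth(params)} is narrowed to approximately
#'   \code{bandwidth/enhancement}.
#' @export
setGeneric("selfDeconvolve", function(x, params = FSDParams())
  standardGeneric("selfDeconvolve"))

#' Restrict a spectrum to a wavenumber window
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{SpectrumSet}.
#' @param upper,lower window bounds in cm^-1 (inclusive); points with
#'   \code{lower <= wavenumber <= upper} are kept.
#' @return Object of the same class restricted to the window.
#' @export
setGeneric("cropWavenumbers", function(x, upper, lower)
  standardGeneric("cropWavenumbers"))

#' Multi-level discrete wavelet decomposition of a spectrum
#'
#' @param x a \linkS4class{Spectrum} or a plain numeric vector.
#' @param config a \code{\link{WaveletFeatureConfig}}.
#' @return A \linkS4class{WaveletDecomposition}.
#' @export
setGeneric("dwtDecompose", function(x, config = WaveletFeatureConfig())
  standardGeneric("dwtDecompose"))

#' Band-averaged wavelet-energy features
#'
#' @param x a \linkS4class{WaveletDecomposition}, \linkS4class{Spectrum}
#'   or \linkS4class{SpectrumSet}.
#' @param config a \code{\link{WaveletFeatureConfig}}.
#' @return For a decomposition or single spectrum, a named numeric vector
#'   of length \code{nBands * length(detailLevels)}; for a set, a matrix
#'   with one row per spectrum.
#' @export
setGeneric("bandEnergyFeatures", function(x, config = WaveletFeatureConfig())
  standardGeneric("bandEnergyFeatures"))
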