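#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "Spectrum", function(x) x@wavenumbers)

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "SpectrumSet",
  function(x) SummarizedExperiment::rowData(x)$wavenumber)

#' @rdname absorbance
#' @export
setMethod("absorbance", "Spectrum", function(x) x@absorbance)

#' @rdname absorbance
#' @export
setMethod("absorbance", "SpectrumSet",
  function(x) SummarizedExperiment::assay(x, "absorbance"))

#' @rdname classLabels
#' @export
setMethod("classLabels", "Spectrum", function(x) x@label)

#' @rdname classLabels
#' @export
setMethod("classLabels", "SpectrumSet",
  function(x) SummarizedExperiment::colData(x)$label)

#' Number of spectra in a set
#' @param x a \linkS4class{SpectrumSet}.
#' @return Integer count.
#' @export
nSpectra <- function(x) ncol(x)

#' Extract one member spectrum from a set
#'
#' @param x a \linkS4class{SpectrumSet}.
#' @param i column index or name.
#' @return A \linkS4class{Spectrum}.
#' @export
getSpectrum <- function(x, i) {
  stopifnot(is(x, "SpectrumSet"))
  Spectrum(wavenumbers(x), absorbance(x)[, i],
           label = classLabels(x)[if (is.character(i))
             match(i, colnames(x)) else i],
           meta = list(id = if (is.character(i)) i else colnames(x)[i]))
}

setMethod("show", "Spectrum", function(object) {
  w <- object@wavenumbers
  cat(sprintf("Spectrum: %d points, %.0f -> %.0f cm-1", length(w),
              w[1L], w[length(w)]))
  if (!is.na(object@label)) cat(sprintf(" [label: %s]", object@label))
  cat(sprintf("\n  absorbance range: %.4g .. %.4g\n",
              min(object@absorbance), max(object@absorbance)))
})

setMethod("show", "SpectrumSet", function(object) {
  w <- wavenumbers(object)
  lab <- classLabels(object)
  cat(sprintf("SpectrumSet: %d spectra x %d points, %.0f -> %.0f cm-1\n",
              ncol(object), length(w), w[1L], w[length(w)]))
  tb <- table(lab, useNA = "ifany")
  cat("  classes:", paste(sprintf("%s (%d)", names(tb), tb),
                          collapse = ", "), "\n")
})

setMethod("show", "FSDParams", function(object) {
  cat(sprintf("FSDParams: enhancement %.3g, bandwidth %.3g cm-1, %s apodization\n",
              object@enhancement, object@bandwidth, object@apodization))
})

setMethod("show", "WaveletFeatureConfig", function(object) {
  cat(sprintf("WaveletFeatureConfig: %s, %d levels, details {%s}, %d bands (%s energy)\n",
              object@wavelet, object@levels,
              paste(object@detailLevels, collapse = ","),
              object@nBands, object@statistic))
})

#' Average replicate measurements into one spectrum
#'
#' Point-wise arithmetic mean of replicate absorbance traces recorded on
#' bit-identical grids (no interpolation is ever performed). The result's
#' metadata records the replicate count.
#'
#' @param replicates list of \linkS4class{Spectrum} objects or a
#'   \linkS4class{SpectrumSet}.
#' @return A \linkS4class{Spectrum} with the averaged absorbance.
#' @examples
#' w <- seq(4000, 650, by = -2)
#' reps <- lapply(1:3, function(i) Spectrum(w, rep(0.1 * i, length(w))))
#' absorbance(averageReplicates(reps))[1]   # 0.2
#' @export
averageReplicates <- function(replicates) {
  if (is(replicates, "SpectrumSet"))
    replicates <- lapply(seq_len(ncol(replicates)),
                         function(i) getSpectrum(replicates, i))
  stopifnot(length(replicates) >= 1L)
  w <- replicates[[1L]]@wavenumbers
  for (s in replicates)
    if (!identical(s@wavenumbers, w))
      stop("replicate grids differ; averaging requires identical grids")
  a <- rowMeans(vapply(replicates, slot, numeric(length(w)), "absorbance"))
  lab <- unique(vapply(replicates, slot, character(1), "label"))
  Spectrum(w, a, label = if (length(lab) == 1L) lab else NA_character_,
           meta = list(replicates = length(replicates)))
}

#' @rdname cropWavenumbers
#' @export
setMethod("cropWavenumbers", "Spectrum", function(x, upper, lower) {
  keep <- x@wavenumbers <= upper & x@wavenumbers >= lower
  if (sum(keep) < 2L) stop("cropping window retains fewer than 2 points")
  Spectrum(x@wavenumbers[keep], x@absorbance[keep], label = x@label,
           meta = x@meta)
})

#' @rdname cropWavenumbers
#' @export
setMethod("cropWavenumbers", "SpectrumSet", function(x, upper, lower) {
  w <- wavenumbers(x)
  keep <- w <= upper & w >= lower
  if (sum(keep) < 2L) stop("cropping window retains fewer than 2 points")
  SpectrumSet(absorbance = absorbance(x)[keep, , drop = FALSE],
              wavenumbers = w[keep], labels = classLabels(x))
})
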