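#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Default wavenumber grid
#'
#' 4000 -> 650 cm^-1 in 2 cm^-1 steps (1676 points), the usual mid-IR
#' ATR acquisition range and resolution.
#'
#' @return Numeric vector, descending.
#' @export
defaultGrid <- function() seq(4000, 650, by = -2)

#' Default three-class band templates
#'
#' Templates emulating three botanically related root materials whose
#' ATR-FTIR fingerprints share every band position and width and differ
#' only in relative band intensities -- the regime in which visual
#' comparison fails and chemometric classification is needed. Each
#' template carries 23 Lorentzian bands: broad O-H (3300 cm^-1), C-H
#' (2920 cm^-1), amide/water (1650 cm^-1) and carbohydrate C-O
#' (1030-1200 cm^-1) envelopes plus sharp fingerprint bands, with
#' per-band amplitude differences of 5-20% between any two classes,
#' regionally coherent (one class is systematically richer in a spectral
#' region, as composition differences produce in practice). The
#' amplitude table ships as \code{extdata/class_templates.csv}.
#'
#' @return List of three \linkS4class{ClassTemplate} objects.
#' @examples
#' tpl <- defaultTemplates()
#' vapply(tpl, function(t) t@name, character(1))
#' @export
defaultTemplates <- function() {
  path <- system.file("extdata", "class_templates.csv",
                      package = "ftirherb", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(unique(tab$class), function(cl)
    ClassTemplate(cl, tab[tab$class == cl,
                          c("center", "fwhm", "amplitude", "shape")]))
}

.lineshape <- function(grid, center, fwhm, amplitude, shape) {
  if (shape == "lorentzian") {
    g <- fwhm / 2
    amplitude * g^2 / ((grid - center)^2 + g^2)
  } else {
    amplitude * exp(-4 * log(2) * (grid - center)^2 / fwhm^2)
  }
}

.renderNoiseless <- function(template, grid) {
  b <- template@bands
  y <- numeric(length(grid))
  for (i in seq_len(nrow(b)))
    y <- y + .lineshape(grid, b$center[i], b$fwhm[i], b$amplitude[i],
                        b$shape[i])
  y
}

#' Render one synthetic spectrum from a class template
#'
#' The noiseless trace is the sum of the template's band lineshapes;
#' degradation then adds a random linear baseline tilt, i.i.d. Gaussian
#' noise per point, and finally a global multiplicative intensity
#' jitter (emulating contact-pressure variation). Reproducible given
#' \code{noise@seed}.
#'
#' @param template a \linkS4class{ClassTemplate}.
#' @param grid wavenumber grid (default \code{\link{defaultGrid}}).
#' @param noise a \code{\link{NoiseModel}}; all-zero sigmas give the
#'   deterministic noiseless render.
#' @return A \linkS4class{Spectrum} labelled with the template name.
#' @export
renderSpectrum <- function(template, grid = defaultGrid(),
                           noise = NoiseModel()) {
  stopifnot(is(template, "ClassTemplate"), is(noise, "NoiseModel"))
  rng <- all(range(template@bands$center) <= max(grid)) &&
         all(range(template@bands$center) >= min(grid))
  if (!rng) stop("band centers must lie within the grid range")
  .withSeed(noise@seed, {
    y <- .renderNoiseless(template, grid)
    slope <- rnorm(1L, 0, noise@baselineSlopeSigma)
    y <- y + slope * (grid - mean(grid))
    y <- y + rnorm(length(grid), 0, noise@additiveSigma)
    y <- y * (1 + rnorm(1L, 0, noise@intensityScaleSigma))
    Spectrum(grid, y, label = template@name)
  })
}

#' Generate a balanced labelled synthetic dataset
#'
#' Renders \code{nPerClass} degraded spectra from each class template on
#' a common grid. Deterministic for a given seed: the same seed yields a
#' bit-identical dataset.
#'
#' @param nPerClass spectra per class (>= 1).
#' @param noise a \code{\link{NoiseModel}}.
#' @param grid common wavenumber grid.
#' @param templates list of \linkS4class{ClassTemplate} objects
#'   (default \code{\link{defaultTemplates}}).
#' @param seed RNG seed; defaults to \code{noise@seed}.
#' @return A \linkS4class{SpectrumSet} of \code{3 * nPerClass} spectra
#'   (for the default three templates).
#' @examples
#' set.seed(1)
#' train <- generateDataset(5, NoiseModel(seed = 11L))
#' table(classLabels(train))
#' @export
generateDataset <- function(nPerClass, noise = NoiseModel(),
                            grid = defaultGrid(),
                            templates = defaultTemplates(),
                            seed = noise@seed) {
  stopifnot(nPerClass >= 1L)
  innerNoise <- NoiseModel(noise@additiveSigma, noise@baselineSlopeSigma,
                           noise@intensityScaleSigma)   # seed NA: use stream
  .withSeed(seed, {
    cols <- list(); labels <- character(0)
    for (tpl in templates) {
      for (i in seq_len(nPerClass)) {
        s <- renderSpectrum(tpl, grid, innerNoise)
        cols[[length(cols) + 1L]] <- s@absorbance
        labels <- c(labels, tpl@name)
      }
    }
    m <- do.call(cbind, cols)
    within <- stats::ave(seq_along(labels), labels, FUN = seq_along)
    colnames(m) <- sprintf("%s_%03d", labels, within)
    SpectrumSet(absorbance = m, wavenumbers = grid, labels = labels)
  })
}
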