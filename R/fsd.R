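#' @include AllClasses.R AllGenerics.R
NULL

# Apodization windows on u = x/L in [0, 1]. "bessel" uses the common
# (1 - u^2)^2 closed-form approximation of the Bessel window.
.apodWindow <- function(u, apodization) {
  w <- switch(apodization,
              boxcar = rep(1, length(u)),
              triangular_squared = (1 - u)^2,
              bessel = (1 - u^2)^2,
              stop("unknown apodization: ", apodization))
  w[u > 1] <- 0
  w
}

# FWHM of the window's own lineshape (its Fourier transform) for unit
# cutoff, found by bisection on the cosine transform; the cutoff L for a
# target resolution r is then c/r. Cached per window.
.apodEnv <- new.env(parent = emptyenv())
.apodFWHMConstant <- function(apodization) {
  if (!is.null(.apodEnv[[apodization]])) return(.apodEnv[[apodization]])
  xs <- seq(0, 1, length.out = 4001L)
  wx <- .apodWindow(xs, apodization)
  ft <- function(nu) {
    integrand <- wx * cos(2 * pi * nu * xs)
    2 * sum((integrand[-1L] + integrand[-length(xs)]) / 2) * (xs[2L] - xs[1L])
  }
  half <- ft(0) / 2
  lo <- 0; hi <- 5
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (ft(mid) > half) lo <- mid else hi <- mid
  }
  .apodEnv[[apodization]] <- 2 * lo
  .apodEnv[[apodization]]
}

.fsdVector <- function(a, step, params) {
  n <- length(a)
  K <- params@enhancement
  w <- params@bandwidth
  m <- mean(a)
  k <- seq_len(n) - 1L
  x <- pmin(k, n - k) / (n * step)          # retardation axis, cm
  if (K == 1 && params@apodization == "boxcar") {
    filt <- rep(1, n)                       # identity configuration
  } else {
    L <- .apodFWHMConstant(params@apodization) * K / w
    filt <- exp(pi * w * x) * .apodWindow(x / L, params@apodization)
  }
  nyq <- filt[which.max(x)]
  if (nyq > 1e6)
    warning(sprintf(paste("self-deconvolution filter gain %.3g at the",
                          "Nyquist bin; noise will dominate"), nyq))
  Re(fft(fft(a - m) * filt, inverse = TRUE)) / n + m
}

#' @rdname selfDeconvolve
#' @export
setMethod("selfDeconvolve", "Spectrum", function(x, params = FSDParams()) {
  w <- x@wavenumbers
  steps <- diff(w)
  if (max(abs(steps - steps[1L])) > 1e-6 * abs(steps[1L]))
    stop("self-deconvolution requires a uniform wavenumber grid")
  Spectrum(w, .fsdVector(x@absorbance, abs(steps[1L]), params),
           label = x@label, meta = c(x@meta, list(fsd = TRUE)))
})

#' @rdname selfDeconvolve
#' @export
setMethod("selfDeconvolve", "SpectrumSet", function(x, params = FSDParams()) {
  w <- wavenumbers(x)
  steps <- diff(w)
  if (max(abs(steps - steps[1L])) > 1e-6 * abs(steps[1L]))
    stop("self-deconvolution requires a uniform wavenumber grid")
  a <- absorbance(x)
  out <- apply(a, 2L, .fsdVector, step = abs(steps[1L]), params = params)
  dimnames(out) <- dimnames(a)
  SpectrumSet(absorbance = out, wavenumbers = w, labels = classLabels(x))
})
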