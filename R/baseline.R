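#' @include AllClasses.R AllGenerics.R
NULL

# Andrew's monotone-chain lower convex hull on (index, y); returns the
# hull vertex indices in increasing order. O(n) amortised.
.lowerHull <- function(y) {
  n <- length(y)
  hull <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    while (m >= 2L) {
      i1 <- hull[m - 1L]; i2 <- hull[m]
      # pop i2 while it lies on or above the chord i1 -> i
      if ((y[i2] - y[i1]) * (i - i2) >= (y[i] - y[i2]) * (i2 - i1))
        m <- m - 1L
      else break
    }
    m <- m + 1L
    hull[m] <- i
  }
  hull[seq_len(m)]
}

.rubberband <- function(y) {
  h <- .lowerHull(y)
  y - approx(h, y[h], xout = seq_along(y))$y
}

.polyBaseline <- function(y, degree) {
  n <- length(y)
  if (degree < 0L || degree >= n)
    stop(sprintf("polynomial degree must be in 0..%d (got %d)",
                 n - 1L, degree))
  if (degree == 0L) return(y - mean(y))
  idx <- seq_len(n)
  fit <- lm(y ~ poly(idx, degree))
  y - as.numeric(predict(fit))
}

.baselineCorrect <- function(a, method, degree) {
  switch(method,
         rubberband = .rubberband(a),
         polynomial = .polyBaseline(a, as.integer(degree)),
         stop("unknown baseline method: ", method))
}

#' @rdname autoBaseline
#' @export
setMethod("autoBaseline", "Spectrum",
  function(x, method = c("rubberband", "polynomial"), degree = 2L) {
    method <- match.arg(method)
    Spectrum(x@wavenumbers, .baselineCorrect(x@absorbance, method, degree),
             label = x@label,
             meta = c(x@meta, list(baseline = method)))
  })

#' @rdname autoBaseline
#' @export
setMethod("autoBaseline", "SpectrumSet",
  function(x, method = c("rubberband", "polynomial"), degree = 2L) {
    method <- match.arg(method)
    a <- absorbance(x)
    corrected <- apply(a, 2L, .baselineCorrect, method = method,
                       degree = degree)
    dimnames(corrected) <- dimnames(a)
    SpectrumSet(absorbance = corrected, wavenumbers = wavenumbers(x),
                labels = classLabels(x))
  })
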