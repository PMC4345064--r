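#' @include AllClasses.R AllGenerics.R
NULL

# Orthonormal Daubechies scaling (low-pass) filters. dbN has 2N taps and
# N vanishing moments; db4 is the package default.
.dbFilters <- list(
  db2 = c(-0.12940952255126037, 0.22414386804201339, 0.83651630373780794,
          0.48296291314453416),
  db3 = c(0.035226291885709533, -0.085441273882026658, -0.13501102001025458,
          0.45987750211849154, 0.80689150931109255, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  db5 = c(0.0033357252854737712, -0.012580751999081999, -0.0062414902127982744,
          0.077571493840045719, -0.032244869584638375, -0.24229488706638203,
          0.13842814590132074, 0.72430852843777294, 0.60382926979718965,
          0.16010239797419293),
  db6 = c(-0.0010773010853084796, 0.0047772575109455108, 0.00055384220116149613,
          -0.03158203931748603, 0.027522865530305727, 0.097501605587323043,
          -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
          0.75113390802109536, 0.49462389039845306, 0.11154074335010947),
  db8 = c(-0.00011747678412476953, 0.00067544940645056933,
          -0.00039174037337694705, -0.0048703529934515741,
          0.0087460940474057766, 0.013981027917398282, -0.044088253930794755,
          -0.017369301001807547, 0.12874742662047847, 0.00047248457391328279,
          -0.28401554296154691, -0.015829105256349306, 0.58535468365420673,
          0.67563073629728976, 0.31287159091429995, 0.054415842243104008))

# Quadrature-mirror high-pass from the low-pass filter.
.qmf <- function(h) {
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1L)
}

# One periodized analysis step (n even). Row n of the analysis operator
# places h[k] at column (2n + k) mod N; with circular wrapping the
# operator is orthogonal for every even N because all even-lag
# autocorrelations of an orthonormal wavelet filter vanish.
.dwtStep <- function(x, h, g) {
  n <- length(x)
  half <- n %/% 2L
  idx0 <- 2L * (seq_len(half) - 1L)
  ca <- numeric(half); cd <- numeric(half)
  for (k in seq_along(h)) {
    xi <- x[((idx0 + (k - 1L)) %% n) + 1L]
    ca <- ca + h[k] * xi
    cd <- cd + g[k] * xi
  }
  list(ca = ca, cd = cd)
}

# Exact transpose of .dwtStep (synthesis).
.idwtStep <- function(ca, cd, h, g) {
  n <- 2L * length(ca)
  x <- numeric(n)
  idx0 <- 2L * (seq_along(ca) - 1L)
  for (k in seq_along(h)) {
    j <- ((idx0 + (k - 1L)) %% n) + 1L
    x[j] <- x[j] + h[k] * ca + g[k] * cd
  }
  x
}

.dwtDecomposeVector <- function(a, config) {
  h <- .dbFilters[[config@wavelet]]
  g <- .qmf(h)
  levels <- config@levels
  n <- length(a)
  maxDepth <- floor(log2(n))
  if (n < 2^levels)
    stop(sprintf(paste("signal of length %d supports at most %d",
                       "decomposition levels (requested %d)"),
                 n, maxDepth, levels))
  details <- vector("list", levels)
  inputLengths <- integer(levels)
  cur <- a
  for (l in seq_len(levels)) {
    inputLengths[l] <- length(cur)
    if (length(cur) %% 2L == 1L)            # pad odd lengths by
      cur <- c(cur, cur[length(cur)])       # repeating the last sample
    st <- .dwtStep(cur, h, g)
    details[[l]] <- st$cd
    cur <- st$ca
  }
  new("WaveletDecomposition", approximation = cur, details = details,
      inputLengths = inputLengths, wavelet = config@wavelet)
}

#' @rdname dwtDecompose
#' @export
setMethod("dwtDecompose", "numeric",
  function(x, config = WaveletFeatureConfig())
    .dwtDecomposeVector(x, config))

#' @rdname dwtDecompose
#' @export
setMethod("dwtDecompose", "Spectrum",
  function(x, config = WaveletFeatureConfig())
    .dwtDecomposeVector(x@absorbance, config))

#' Reconstruct a signal from its wavelet decomposition
#'
#' Inverse of \code{\link{dwtDecompose}}; exact (to numerical precision)
#' for every input length thanks to the recorded pre-padding lengths.
#'
#' @param decomp a \linkS4class{WaveletDecomposition}.
#' @return Numeric vector of the original signal length.
#' @export
waveletReconstruct <- function(decomp) {
  stopifnot(is(decomp, "WaveletDecomposition"))
  h <- .dbFilters[[decomp@wavelet]]
  g <- .qmf(h)
  cur <- decomp@approximation
  for (l in rev(seq_along(decomp@details))) {
    cur <- .idwtStep(cur, decomp@details[[l]], h, g)
    cur <- cur[seq_len(decomp@inputLengths[l])]   # undo padding
  }
  cur
}

setMethod("show", "WaveletDecomposition", function(object) {
  lens <- vapply(object@details, length, integer(1))
  cat(sprintf("WaveletDecomposition (%s): approximation %d, details %s\n",
              object@wavelet, length(object@approximation),
              paste(lens, collapse = "/")))
})

# Contiguous band boundaries for one detail signal: either the explicit
# interior cut points from config, or equal-width bands.
.bandBreaks <- function(n, level, config) {
  key <- as.character(level)
  if (length(config@bandEdges) && !is.null(config@bandEdges[[key]])) {
    cuts <- sort(as.integer(config@bandEdges[[key]]))
    breaks <- c(0L, cuts, n)
  } else {
    breaks <- round(seq(0L, n, length.out = config@nBands + 1L))
  }
  if (any(diff(breaks) < 1L))
    stop(sprintf("empty feature band at detail level %d (length %d)",
                 level, n))
  breaks
}

.bandEnergiesOf <- function(decomp, config) {
  out <- numeric(0)
  for (lev in config@detailLevels) {
    d <- decomp@details[[lev]]
    if (is.null(d))
      stop("detail level ", lev, " absent from decomposition")
    breaks <- .bandBreaks(length(d), lev, config)
    nb <- length(breaks) - 1L
    for (b in seq_len(nb)) {
      seg <- d[(breaks[b] + 1L):breaks[b + 1L]]
      e <- if (config@statistic == "mean") mean(seg^2) else sum(seg^2)
      out <- c(out, setNames(e, sprintf("d%d.b%d", lev, b)))
    }
  }
  out
}

#' @rdname bandEnergyFeatures
#' @export
setMethod("bandEnergyFeatures", "WaveletDecomposition",
  function(x, config = WaveletFeatureConfig()) .bandEnergiesOf(x, config))

#' @rdname bandEnergyFeatures
#' @export
setMethod("bandEnergyFeatures", "Spectrum",
  function(x, config = WaveletFeatureConfig())
    .bandEnergiesOf(dwtDecompose(x, config), config))

#' @rdname bandEnergyFeatures
#' @export
setMethod("bandEnergyFeatures", "SpectrumSet",
  function(x, config = WaveletFeatureConfig()) {
    a <- absorbance(x)
    feats <- t(apply(a, 2L, function(col)
      .bandEnergiesOf(.dwtDecomposeVector(col, config), config)))
    rownames(feats) <- colnames(a)
    attr(feats, "labels") <- classLabels(x)
    attr(feats, "configDigest") <- configDigest(config)
    feats
  })
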