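# Shared fixtures and independent oracles used across the suite.

# A single Lorentzian band rendered directly (independent of the
# package's template machinery).
lorentzianTrace <- function(grid, center, fwhm, amplitude = 1) {
  g <- fwhm / 2
  amplitude * g^2 / ((grid - center)^2 + g^2)
}

# Numeric FWHM of a single-peaked trace by linear interpolation of the
# half-maximum crossings.
measureFWHM <- function(w, y) {
  i <- which.max(y)
  h <- y[i] / 2
  l <- max(which(y[seq_len(i)] < h))
  r <- i - 1L + min(which(y[i:length(y)] < h))
  xl <- approx(y[c(l, l + 1L)], w[c(l, l + 1L)], xout = h)$y
  xr <- approx(y[c(r - 1L, r)], w[c(r - 1L, r)], xout = h)$y
  abs(xl - xr)
}

# Indices of strict local maxima of a trace.
localMaxima <- function(y) {
  n <- length(y)
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] > y[3:n]) + 1L
}

# Brute-force 1-nearest-neighbour with ties broken by class order of
# first appearance (the same rule the PNN uses).
bruteForce1NN <- function(trainX, trainLabels, x) {
  d2 <- colSums((t(trainX) - x)^2)
  classes <- unique(trainLabels)
  best <- which(d2 == min(d2))
  cand <- classes[classes %in% trainLabels[best]]
  cand[1L]
}

cosineSimilarity <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Total energy of a wavelet decomposition (brute-force coefficient sum).
decompositionEnergy <- function(dec) {
  sum(dec@approximation^2) + sum(vapply(dec@details,
                                        function(d) sum(d^2), numeric(1)))
}
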