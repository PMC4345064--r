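test_that("default templates share geometry and differ only in amplitude", {
  tpl <- defaultTemplates()
  expect_length(tpl, 3L)
  b1 <- tpl[[1]]@bands; b2 <- tpl[[2]]@bands; b3 <- tpl[[3]]@bands
  expect_identical(b1$center, b2$center)
  expect_identical(b1$center, b3$center)
  expect_identical(b1$fwhm, b2$fwhm)
  expect_identical(b1$fwhm, b3$fwhm)
  expect_true(all(c(3300, 2920, 1650, 1400, 1100, 1030) %in% b1$center))
  relDiff <- function(a, b) abs(a - b) / pmax(a, b)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    rd <- relDiff(tpl[[pair[1]]]@bands$amplitude,
                  tpl[[pair[2]]]@bands$amplitude)
    expect_lte(max(rd), 0.20)
    expect_gte(min(rd), 0.05)
  }
})

test_that("noiseless class fingerprints are nearly collinear", {
  tpl <- defaultTemplates()
  zero <- NoiseModel(0, 0, 0)
  traces <- lapply(tpl, function(t) absorbance(renderSpectrum(t, noise = zero)))
  expect_gte(cosineSimilarity(traces[[1]], traces[[2]]), 0.95)
  expect_gte(cosineSimilarity(traces[[1]], traces[[3]]), 0.95)
  expect_gte(cosineSimilarity(traces[[2]], traces[[3]]), 0.95)
  for (tr in traces) expect_gte(min(tr), 0)
})

test_that("noiseless renders put an apex within one grid step of each band", {
  grid <- defaultGrid()
  step <- abs(grid[2] - grid[1])
  zero <- NoiseModel(0, 0, 0)
  for (t in defaultTemplates()) {
    y <- absorbance(renderSpectrum(t, grid, zero))
    apexes <- grid[localMaxima(y)]
    for (ctr in t@bands$center)
      expect_lte(min(abs(apexes - ctr)), step + 1e-9)
  }
})

test_that("rendering is reproducible and additive noise has the stated scale", {
  t1 <- defaultTemplates()[[1]]
  nm <- NoiseModel(seed = 99L)
  expect_identical(absorbance(renderSpectrum(t1, noise = nm)),
                   absorbance(renderSpectrum(t1, noise = nm)))
  clean <- absorbance(renderSpectrum(t1, noise = NoiseModel(0, 0, 0)))
  noisy <- absorbance(renderSpectrum(t1,
    noise = NoiseModel(0.005, 0, 0, seed = 7L)))
  expect_lt(abs(sd(noisy - clean) - 0.005) / 0.005, 0.10)  # 1676 points
})

test_that("generateDataset is balanced, labelled and seed-deterministic", {
  ds <- generateDataset(60, NoiseModel(seed = 1L))
  expect_identical(nSpectra(ds), 180L)
  expect_true(all(table(classLabels(ds)) == 60L))

  tplNames <- vapply(defaultTemplates(), function(t) t@name, character(1))
  pure <- generateDataset(1, NoiseModel(0, 0, 0), seed = 1L)
  zero <- NoiseModel(0, 0, 0)
  for (i in seq_len(3))
    expect_equal(absorbance(pure)[, i],
                 absorbance(renderSpectrum(defaultTemplates()[[i]],
                                           noise = zero)),
                 ignore_attr = TRUE)
  expect_identical(classLabels(pure), tplNames)

  a <- generateDataset(5, NoiseModel(seed = 123L))
  b <- generateDataset(5, NoiseModel(seed = 123L))
  c <- generateDataset(5, NoiseModel(seed = 124L))
  expect_identical(absorbance(a), absorbance(b))
  expect_false(isTRUE(all.equal(absorbance(a), absorbance(c))))
})

test_that("classes are recoverable by nearest centroid on raw spectra", {
  # sanity floor for the pipeline to beat: even plain nearest-centroid
  # separates the classes under additive noise alone. Baseline drift is
  # excluded here -- a raw Euclidean rule cannot absorb a random tilt
  # (removing it is exactly the job of the pipeline's baseline stage).
  nm <- NoiseModel(additiveSigma = 0.01, baselineSlopeSigma = 0,
                   intensityScaleSigma = 0.01, seed = 5L)
  train <- generateDataset(10, nm)
  test <- generateDataset(20, NoiseModel(additiveSigma = 0.01,
                                         baselineSlopeSigma = 0,
                                         intensityScaleSigma = 0.01,
                                         seed = 6L))
  classes <- unique(classLabels(train))
  centroids <- vapply(classes, function(cl)
    rowMeans(absorbance(train)[, classLabels(train) == cl, drop = FALSE]),
    numeric(length(defaultGrid())))
  pred <- apply(absorbance(test), 2L, function(y)
    classes[which.min(colSums((centroids - y)^2))])
  expect_gt(100 * mean(pred == classLabels(test)), 90)
})
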