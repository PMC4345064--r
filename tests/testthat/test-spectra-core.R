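test_that("Spectrum normalises grid direction and enforces invariants", {
  s <- Spectrum(c(4000, 3998, 3996), c(0.1, 0.2, 0.1))
  expect_identical(wavenumbers(s), c(4000, 3998, 3996))
  expect_identical(absorbance(s), c(0.1, 0.2, 0.1))

  asc <- Spectrum(c(3996, 3998, 4000), c(0.1, 0.2, 0.1))
  expect_identical(wavenumbers(asc), wavenumbers(s))
  expect_identical(absorbance(asc), rev(c(0.1, 0.2, 0.1)))

  expect_error(Spectrum(c(4000, 4000, 3996), c(1, 2, 3)), "monotonic")
  expect_error(Spectrum(c(4000, 3998), c(1, NaN)), "finite")
  expect_error(Spectrum(4000, 1), "2 points|equal length")
})

test_that("CSV and JCAMP round trips preserve absorbance to 1e-6", {
  set.seed(11)
  w <- seq(4000, 650, by = -2)
  s <- Spectrum(w, abs(rnorm(length(w), 0.3, 0.1)), label = "rt")
  for (fmt in c("csv", "jcamp")) {
    path <- file.path(tempdir(), paste0("rt.", fmt))
    writeSpectrum(s, path, format = fmt)
    back <- readSpectrum(path, format = fmt)
    expect_identical(wavenumbers(back), wavenumbers(s))
    expect_lt(max(abs(absorbance(back) - absorbance(s))), 1e-6)
  }
})

test_that("JCAMP XYDATA=(X++(Y..Y)) tables are parsed", {
  path <- file.path(tempdir(), "xyd.jdx")
  writeLines(c(
    "##TITLE=synthetic xydata fixture",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##FIRSTX=4000", "##LASTX=3990", "##NPOINTS=6",
    "##XFACTOR=1", "##YFACTOR=0.001", "##DELTAX=-2",
    "##XYDATA=(X++(Y..Y))",
    "4000 100 200 300",
    "3994 400 500 600",
    "##END="), path)
  s <- readSpectrum(path, format = "jcamp")
  expect_identical(wavenumbers(s), seq(4000, 3990, by = -2))
  expect_equal(absorbance(s), c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
})

test_that("malformed inputs produce parse errors naming the record", {
  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("wavenumber,absorbance", "4000,0.1", "oops,xx", "3996,0.1"),
             bad)
  expect_error(readSpectrum(bad, format = "csv"), "line 3")
  expect_error(readSpectrum(file.path(tempdir(), "nothere.csv")),
               "not found")
})

test_that("replicate averaging is a point-wise mean on identical grids", {
  w <- seq(4000, 650, by = -2)
  a <- Spectrum(w, rep(0, length(w)))
  b <- Spectrum(w, rep(1, length(w)))
  expect_equal(absorbance(averageReplicates(list(b, b, b))),
               absorbance(b))
  expect_equal(absorbance(averageReplicates(list(a, b))),
               rep(0.5, length(w)))
  expect_identical(absorbance(averageReplicates(list(a, b))),
                   absorbance(averageReplicates(list(b, a))))
  expect_identical(averageReplicates(list(a, b, b))@meta$replicates, 3L)
  shifted <- Spectrum(w + 1, rep(1, length(w)))
  expect_error(averageReplicates(list(a, shifted)), "identical grids")
})

test_that("averaging three noisy replicates reduces noise by sqrt(3)", {
  set.seed(42)
  w <- seq(2998, 1000, by = -2)           # 1000 points
  truth <- lorentzianTrace(w, 2000, 200, 0.5)
  reps <- lapply(1:3, function(i)
    Spectrum(w, truth + rnorm(length(w), 0, 0.01)))
  resid <- absorbance(averageReplicates(reps)) - truth
  expect_lt(abs(sd(resid) - 0.01 / sqrt(3)) / (0.01 / sqrt(3)), 0.10)
})

test_that("rubberband baseline removes constants and linear ramps", {
  w <- seq(4000, 650, by = -2)
  flat <- Spectrum(w, rep(0.3, length(w)))
  expect_lt(max(abs(absorbance(autoBaseline(flat)))), 1e-12)
  ramp <- Spectrum(w, seq(0, 1, length.out = length(w)))
  expect_lt(max(abs(absorbance(autoBaseline(ramp)))), 1e-9)
})

test_that("rubberband recovers a peak sitting on a linear ramp", {
  w <- seq(4000, 650, by = -2)
  peak <- 0.8 * exp(-4 * log(2) * (w - 1600)^2 / 120^2)
  ramp <- 0.2 + 1e-4 * (4000 - w)
  corrected <- absorbance(autoBaseline(Spectrum(w, peak + ramp)))
  expect_lt(abs(max(corrected) - max(peak)) / max(peak), 0.01)
  expect_gte(min(corrected), -1e-9)
})

test_that("baseline correction is idempotent and validates its degree", {
  set.seed(3)
  w <- seq(4000, 650, by = -2)
  s <- Spectrum(w, lorentzianTrace(w, 1500, 150, 0.6) +
                  1e-4 * (4000 - w) + abs(rnorm(length(w), 0, 0.01)))
  once <- autoBaseline(s)
  twice <- autoBaseline(once)
  expect_lt(max(abs(absorbance(twice) - absorbance(once))), 1e-9)
  p1 <- autoBaseline(s, "polynomial", degree = 3L)
  p2 <- autoBaseline(p1, "polynomial", degree = 3L)
  expect_lt(max(abs(absorbance(p2) - absorbance(p1))), 1e-9)
  expect_error(autoBaseline(s, "polynomial", degree = -1L), "degree")
  expect_error(autoBaseline(s, "polynomial", degree = length(w)), "degree")
})

test_that("SpectrumSet shares one grid and round-trips members", {
  w <- seq(4000, 650, by = -2)
  sp <- lapply(1:3, function(i)
    Spectrum(w, lorentzianTrace(w, 1500, 100, 0.1 * i),
             label = paste0("c", i)))
  set <- SpectrumSet(sp)
  expect_identical(nSpectra(set), 3L)
  expect_identical(classLabels(set), c("c1", "c2", "c3"))
  expect_identical(absorbance(getSpectrum(set, 2)), absorbance(sp[[2]]))
  s2 <- Spectrum(w[-1], absorbance(sp[[1]])[-1])
  expect_error(SpectrumSet(list(sp[[1]], s2)), "identical wavenumber grid")
  cropped <- cropWavenumbers(set, 2000, 650)
  expect_identical(length(wavenumbers(cropped)), 676L)
})
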