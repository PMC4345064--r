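# ftirherb

Authentication of herbal raw materials from their ATR-FTIR absorbance
fingerprints.

Closely related medicinal species — e.g. a pharmacopoeia root herb and
its cheaper lookalike relatives — share essentially every infrared band
position because they contain the same major constituents; their spectra
differ only in relative band intensities and are not separable by eye.
`ftirherb` implements the chemometric chain that makes them separable:

1. **Automatic baseline correction** — rubberband (lower convex hull)
   or polynomial detrend.
2. **Fourier self-deconvolution (FSD)** — narrows overlapped bands by
   the interferogram weighting `exp(pi*w*|x|)` with a compact
   re-apodization window; the *bandwidth* `w` (assumed Lorentzian FWHM,
   default 77.0 cm⁻¹) and *enhancement* `K` (FWHM reduction ratio,
   default 3.5) follow vendor-dial semantics. Peak positions and areas
   are preserved; a matched band narrows to `w/K`.
3. **Wavelet-energy features** — periodized orthonormal Daubechies DWT
   (default `db4`, 5 levels); for detail levels {2, 3, 4} the
   coefficient axis is split into 3 contiguous bands and each feature is
   the mean squared coefficient in one band: 9 features per spectrum.
4. **Probabilistic neural network (PNN)** — every training vector is a
   pattern-layer centre; the summation layer pools a Gaussian Parzen
   kernel per class,

   `H_k(x) = sum_i exp(-||x - c_ki||^2 / (2 sigma^2))`,

   the output layer computes `Y_j = sum_k w_jk H_k(x)` (default
   `w_jj = 1/n_j`), and the predicted class is `argmax_j Y_j`. The
   bandwidth `sigma` is chosen by stratified cross-validation.

Because no public spectra exist for the motivating study, the package
ships a first-class synthetic generator: three class templates sharing
all 23 band centers/widths and differing only in amplitudes by 5–20% per
band (noiseless cosine similarity > 0.99), degraded by additive noise,
baseline tilt and intensity jitter.

## Worked example

```r
library(ftirherb)

noise <- NoiseModel(additiveSigma = 0.005)   # absorbance units
train <- generateDataset(60,  noise, seed = 1L)    # 180 spectra
test  <- generateDataset(100, noise, seed = 1001L) # 300 spectra

report <- evaluatePipeline(train, test, PipelineConfig(seed = 1L))
show(report)
```

```
EvaluationReport (config 9f24d95e, seed 1, sigma 0.1)
  overall accuracy: 100.0%
  radix_bupleuri: 100.0%
  b_smithii: 100.0%
  b_bicaule: 100.0%
confusion matrix:
                predicted
true             radix_bupleuri b_smithii b_bicaule
  radix_bupleuri            100         0         0
  b_smithii                   0       100         0
  b_bicaule                   0         0       100
```

Each row of the confusion matrix is a true class of 100 held-out test
spectra; the diagonal counts correct assignments. `sigma 0.1` is the
Parzen bandwidth selected by 5-fold cross-validation on the training
features; the config digest identifies the exact pipeline settings.

Single stages are exported too:

```r
s  <- readSpectrum("sample.jdx")                  # or CSV
s  <- autoBaseline(s)                             # rubberband
s  <- cropWavenumbers(s, 2000, 650)               # analysis window
sd <- selfDeconvolve(s, FSDParams(3.5, 77.0))     # band narrowing
fv <- bandEnergyFeatures(sd)                      # 9 energies
```

A thin command-line front end with `simulate` / `fsd` / `features` /
`train` / `classify` / `evaluate` subcommands lives at
`inst/scripts/ftirherb-cli.R`.

## Documentation

The methods vignette (`vignettes/ftir-authentication.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, the numerical choices, what the synthetic generator does and
does not emulate, and known limitations.
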