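#' @include AllClasses.R AllGenerics.R baseline.R fsd.R dwt.R pnn.R
NULL

.stage <- function(stage, id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for spectrum '%s': %s", stage, id,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the preprocessing and feature-extraction pipeline
#'
#' Applies the stages in fixed order: automatic baseline correction,
#' restriction to the analysis window, optional Fourier
#' self-deconvolution, multi-level wavelet decomposition, and
#' band-energy feature extraction. Errors are reported with the failing
#' stage and spectrum id.
#'
#' @param spectra a \linkS4class{SpectrumSet} on a common grid.
#' @param config a \code{\link{PipelineConfig}}.
#' @return \code{data.frame} with one row per spectrum: \code{label}
#'   plus one column per feature; the pipeline digest is attached as
#'   attribute \code{"configDigest"}.
#' @examples
#' ds <- generateDataset(3, NoiseModel(seed = 7L))
#' dim(runPipeline(ds, PipelineConfig()))
#' @export
runPipeline <- function(spectra, config = PipelineConfig()) {
  stopifnot(is(spectra, "SpectrumSet"), is(config, "PipelineConfig"))
  ids <- colnames(spectra)
  labels <- classLabels(spectra)
  w <- wavenumbers(spectra)
  a <- absorbance(spectra)
  keep <- if (all(is.finite(config@region)))
    w <= config@region[1L] & w >= config@region[2L] else rep(TRUE, length(w))
  if (sum(keep) < 2^config@waveletConfig@levels)
    stop("analysis window too short for the requested wavelet depth")
  step <- abs(w[2L] - w[1L])
  feats <- NULL
  for (i in seq_along(ids)) {
    y <- .stage("baseline", ids[i],
                .baselineCorrect(a[, i], config@baselineMethod,
                                 config@baselineDegree))
    y <- y[keep]
    if (config@fsdEnabled)
      y <- .stage("fsd", ids[i], .fsdVector(y, step, config@fsdParams))
    dec <- .stage("dwt", ids[i],
                  .dwtDecomposeVector(y, config@waveletConfig))
    fv <- .stage("features", ids[i],
                 .bandEnergiesOf(dec, config@waveletConfig))
    if (is.null(feats))
      feats <- matrix(NA_real_, length(ids), length(fv),
                      dimnames = list(ids, names(fv)))
    feats[i, ] <- fv
  }
  out <- data.frame(label = labels, feats, check.names = FALSE)
  attr(out, "configDigest") <- configDigest(config)
  out
}

#' Train on one spectrum set and evaluate on another
#'
#' Runs \code{\link{runPipeline}} on both sets with the same
#' configuration, selects the PNN bandwidth by cross-validation on the
#' training features when \code{config@sigma} is \code{NA}, fits the
#' PNN on the training set and reports per-class accuracy, overall
#' accuracy and the confusion matrix on the test set. Deterministic
#' given \code{config@seed}.
#'
#' @param train,test \linkS4class{SpectrumSet}s with labels; every test
#'   class must be present in training.
#' @param config a \code{\link{PipelineConfig}}.
#' @return An \linkS4class{EvaluationReport}.
#' @export
evaluatePipeline <- function(train, test, config = PipelineConfig()) {
  trLab <- classLabels(train)
  teLab <- classLabels(test)
  if (anyNA(trLab) || anyNA(teLab))
    stop("train and test spectra must all carry class labels")
  missing <- setdiff(unique(teLab), unique(trLab))
  if (length(missing))
    stop("class absent from training data: ",
         paste(missing, collapse = ", "))
  trF <- runPipeline(train, config)
  teF <- runPipeline(test, config)
  X <- .asFeatureMatrix(trF)
  sigma <- config@sigma
  if (is.na(sigma))
    sigma <- as.numeric(selectSigma(X, trLab, sigmas = config@sigmaGrid,
                                    folds = config@folds,
                                    standardize = config@standardize,
                                    seed = config@seed))
  model <- pnnFit(X, trLab, sigma = sigma,
                  standardize = config@standardize)
  pred <- pnnClassify(model, .asFeatureMatrix(teF))$label
  classes <- unique(trLab)
  confusion <- table(factor(teLab, classes), factor(pred, classes))
  confusion <- unclass(as.matrix(confusion))
  names(dimnames(confusion)) <- c("true", "predicted")
  perClass <- 100 * diag(confusion) / rowSums(confusion)
  overall <- 100 * sum(diag(confusion)) / sum(confusion)
  new("EvaluationReport", confusion = confusion,
      perClassAccuracy = perClass, overallAccuracy = overall,
      sigma = sigma, configDigest = configDigest(config),
      seed = config@seed)
}

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (config %s, seed %d, sigma %.4g)\n",
              object@configDigest, object@seed, object@sigma))
  cat(sprintf("  overall accuracy: %.1f%%\n", object@overallAccuracy))
  for (cl in names(object@perClassAccuracy))
    cat(sprintf("  %s: %.1f%%\n", cl, object@perClassAccuracy[cl]))
  cat("confusion matrix:\n")
  print(object@confusion)
})

#' Accessors for evaluation reports
#'
#' @param report an \linkS4class{EvaluationReport}.
#' @return \code{perClassAccuracy}: named numeric in percent;
#'   \code{overallAccuracy}: numeric percent; \code{confusionMatrix}:
#'   true-by-predicted count matrix.
#' @export
perClassAccuracy <- function(report) report@perClassAccuracy

#' @rdname perClassAccuracy
#' @export
overallAccuracy <- function(report) report@overallAccuracy

#' @rdname perClassAccuracy
#' @export
confusionMatrix <- function(report) report@confusion

# ---- flat config files ----------------------------------------------------

#' Read / write a pipeline configuration as a flat key/value file
#'
#' A simple \code{key: value} format (one setting per line, \code{#}
#' comments) fully determining a run; every field of
#' \code{\link{PipelineConfig}} has a key of the same name, with
#' \code{fsdParams} and \code{waveletConfig} flattened as
#' \code{fsd.enhancement}, \code{wavelet.levels}, etc.
#'
#' @param path file path.
#' @param config a \code{\link{PipelineConfig}} (for writing).
#' @return \code{readPipelineConfig}: a \code{PipelineConfig};
#'   \code{writePipelineConfig}: \code{path}, invisibly.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:=]+)[:=](.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    kv[[trimws(m[2L])]] <- trimws(m[3L])
  }
  g <- function(key, default, fn = identity)
    if (!is.null(kv[[key]])) fn(kv[[key]]) else default
  nums <- function(v) as.numeric(strsplit(v, "[, ]+")[[1L]])
  ints <- function(v) as.integer(nums(v))
  PipelineConfig(
    baselineMethod = g("baselineMethod", "rubberband"),
    baselineDegree = g("baselineDegree", 2L, as.integer),
    fsdEnabled = g("fsdEnabled", TRUE, function(v)
      toupper(v) %in% c("TRUE", "YES", "1")),
    fsdParams = FSDParams(
      enhancement = g("fsd.enhancement", 3.5, as.numeric),
      bandwidth = g("fsd.bandwidth", 77.0, as.numeric),
      apodization = g("fsd.apodization", "triangular_squared")),
    region = g("region", c(2000, 650), nums),
    waveletConfig = WaveletFeatureConfig(
      wavelet = g("wavelet.name", "db4"),
      levels = g("wavelet.levels", 5L, as.integer),
      detailLevels = g("wavelet.detailLevels", 2:4, ints),
      nBands = g("wavelet.nBands", 3L, as.integer),
      statistic = g("wavelet.statistic", "mean")),
    sigma = g("sigma", NA_real_, as.numeric),
    sigmaGrid = g("sigmaGrid", c(0.1, 0.2, 0.5, 1, 2), nums),
    folds = g("folds", 5L, as.integer),
    standardize = g("standardize", TRUE, function(v)
      toupper(v) %in% c("TRUE", "YES", "1")),
    seed = g("seed", 1L, as.integer))
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(config, path) {
  wc <- config@waveletConfig; fp <- config@fsdParams
  writeLines(c(
    "# ftirherb pipeline configuration v1",
    paste0("baselineMethod: ", config@baselineMethod),
    paste0("baselineDegree: ", config@baselineDegree),
    paste0("fsdEnabled: ", config@fsdEnabled),
    paste0("fsd.enhancement: ", fp@enhancement),
    paste0("fsd.bandwidth: ", fp@bandwidth),
    paste0("fsd.apodization: ", fp@apodization),
    paste0("region: ", paste(config@region, collapse = ", ")),
    paste0("wavelet.name: ", wc@wavelet),
    paste0("wavelet.levels: ", wc@levels),
    paste0("wavelet.detailLevels: ",
           paste(wc@detailLevels, collapse = ", ")),
    paste0("wavelet.nBands: ", wc@nBands),
    paste0("wavelet.statistic: ", wc@statistic),
    paste0("sigma: ", config@sigma),
    paste0("sigmaGrid: ", paste(config@sigmaGrid, collapse = ", ")),
    paste0("folds: ", config@folds),
    paste0("standardize: ", config@standardize),
    paste0("seed: ", config@seed)), path)
  invisible(path)
}
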