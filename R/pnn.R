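#' @include AllClasses.R utils.R
NULL

.asFeatureMatrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[, setdiff(colnames(features), "label"),
                         drop = FALSE]
    features <- as.matrix(features)
  }
  storage.mode(features) <- "double"
  features
}

#' Fit a probabilistic neural network
#'
#' Training is deterministic storage: every training feature vector
#' becomes a pattern-layer centre. The summation layer pools a Gaussian
#' Parzen kernel over each class's centres,
#' \deqn{H_k(x) = \sum_{i=1}^{n_k} \exp(-\|x - c_{ki}\|^2 / 2\sigma^2),}
#' and the output layer computes \eqn{Y_j = \sum_k w_{jk} H_k(x)} with
#' default weights \eqn{w_{jj} = 1/n_j} (own-class units only).
#'
#' @param features n-by-p matrix (or data.frame) of feature vectors.
#' @param labels length-n class labels (>= 2 distinct, none empty).
#' @param sigma kernel bandwidth (> 0).
#' @param standardize z-score each feature on the training data before
#'   computing kernel distances (recommended: band energies span orders
#'   of magnitude across scales).
#' @param weights optional M-by-M output weight matrix; default
#'   \code{diag(1/n_k)}.
#' @return A \linkS4class{PNNModel}.
#' @examples
#' X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 3), 10))
#' m <- pnnFit(X, rep(c("a", "b"), each = 10), sigma = 1)
#' pnnClassify(m, c(3, 3))@label
#' @export
pnnFit <- function(features, labels, sigma = 1, standardize = TRUE,
                   weights = NULL) {
  X <- .asFeatureMatrix(features)
  if (anyNA(X) || !all(is.finite(X)))
    stop("features must be finite and free of NA")
  if (length(labels) != nrow(X))
    stop("one label per feature vector is required")
  if (sigma <= 0) stop("sigma must be > 0")
  classNames <- unique(as.character(labels))
  if (length(classNames) < 2L) stop("at least 2 classes are required")
  ki <- match(as.character(labels), classNames)
  nk <- tabulate(ki, length(classNames))
  if (any(nk == 0L)) stop("every class needs at least one sample")
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    X <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  }
  if (is.null(weights)) weights <- diag(1 / nk)
  new("PNNModel", centers = X, classIndex = ki, classNames = classNames,
      sigma = sigma, weights = weights, standardize = standardize,
      center = ctr, scale = scl)
}

.prepareX <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != ncol(model@centers))
    stop(sprintf("feature dimension mismatch: model has %d, input has %d",
                 ncol(model@centers), length(x)))
  if (model@standardize) (x - model@center) / model@scale else x
}

.sqDistances <- function(model, z) {
  d <- sweep(model@centers, 2L, z)
  rowSums(d * d)
}

#' Pattern-layer response of a PNN
#'
#' Raw summation-layer outputs \eqn{H_k(x)}; each lies in
#' \eqn{(0, n_k]}, reaching \eqn{n_k} only when the kernel flattens
#' (large sigma) and 1 when \eqn{x} coincides with a class's sole
#' centre. Underflows to 0 for very small sigma; classification uses a
#' numerically shifted version internally.
#'
#' @param model a \linkS4class{PNNModel}.
#' @param x feature vector of the model's dimension.
#' @return Named numeric vector of per-class responses.
#' @export
patternResponse <- function(model, x) {
  z <- .prepareX(model, x)
  d2 <- .sqDistances(model, z)
  kern <- exp(-d2 / (2 * model@sigma^2))
  H <- vapply(seq_along(model@classNames),
              function(k) sum(kern[model@classIndex == k]), numeric(1))
  setNames(H, model@classNames)
}

#' Classify a feature vector with a PNN
#'
#' Output scores \eqn{Y_j = \sum_k w_{jk} H_k(x)}; the predicted label
#' is \eqn{\arg\max_j Y_j} with deterministic ties broken by class
#' order. Kernels are rescaled by the nearest-centre distance before
#' summation, which leaves the argmax and the normalised posteriors
#' unchanged but keeps the computation finite for arbitrarily small
#' sigma (in which limit the classifier reduces to 1-nearest-neighbour).
#'
#' @param model a \linkS4class{PNNModel}.
#' @param x a feature vector, or a matrix with one vector per row.
#' @return A \linkS4class{PNNPrediction} for a single vector; for a
#'   matrix, a data.frame with a \code{label} column and per-class
#'   posterior columns.
#' @export
pnnClassify <- function(model, x) {
  if (is.matrix(x) || is.data.frame(x)) {
    X <- .asFeatureMatrix(x)
    preds <- lapply(seq_len(nrow(X)), function(i) pnnClassify(model, X[i, ]))
    post <- t(vapply(preds, slot, numeric(length(model@classNames)),
                     "posteriors"))
    colnames(post) <- model@classNames
    return(data.frame(label = vapply(preds, slot, character(1), "label"),
                      post, check.names = FALSE))
  }
  z <- .prepareX(model, x)
  d2 <- .sqDistances(model, z)
  kern <- exp(-(d2 - min(d2)) / (2 * model@sigma^2))   # shift-invariant
  H <- vapply(seq_along(model@classNames),
              function(k) sum(kern[model@classIndex == k]), numeric(1))
  Y <- as.numeric(model@weights %*% H)
  post <- if (sum(Y) > 0) Y / sum(Y) else rep(1 / length(Y), length(Y))
  lab <- model@classNames[which.max(Y)]    # which.max: first max wins
  raw <- Y * exp(-min(d2) / (2 * model@sigma^2))   # undo the shift; may
  new("PNNPrediction", label = lab,               # underflow to 0
      scores = setNames(raw, model@classNames),
      posteriors = setNames(post, model@classNames))
}

setMethod("show", "PNNModel", function(object) {
  nk <- tabulate(object@classIndex, length(object@classNames))
  cat(sprintf("PNNModel: %d classes, sigma %.4g%s\n  centres: %s\n",
              length(object@classNames), object@sigma,
              if (object@standardize) ", standardized features" else "",
              paste(sprintf("%s (%d)", object@classNames, nk),
                    collapse = ", ")))
})

setMethod("show", "PNNPrediction", function(object) {
  cat(sprintf("PNNPrediction: %s\n  posteriors: %s\n", object@label,
              paste(sprintf("%s %.3f", names(object@posteriors),
                            object@posteriors), collapse = ", ")))
})

#' Select the kernel bandwidth by stratified cross-validation
#'
#' Evaluates each candidate sigma by k-fold cross-validated accuracy
#' (folds stratified by class, deterministic given \code{seed}) and
#' returns the best; ties go to the smallest sigma.
#'
#' @param features n-by-p feature matrix.
#' @param labels class labels.
#' @param sigmas candidate bandwidths (>= 2 values).
#' @param folds number of folds (>= 2; every class needs at least
#'   \code{folds} samples).
#' @param standardize passed to \code{\link{pnnFit}}.
#' @param seed RNG seed for the fold assignment.
#' @return The selected bandwidth, with the per-candidate mean CV
#'   accuracies attached as attribute \code{"accuracy"}.
#' @export
selectSigma <- function(features, labels, sigmas = c(0.1, 0.2, 0.5, 1, 2),
                        folds = 5L, standardize = TRUE, seed = 1L) {
  X <- .asFeatureMatrix(features)
  labels <- as.character(labels)
  sigmas <- sort(as.numeric(sigmas))
  if (length(sigmas) < 2L) stop("at least 2 candidate sigmas are required")
  if (folds < 2L) stop("folds must be >= 2")
  counts <- table(labels)
  if (any(counts < folds))
    stop(sprintf("class '%s' has %d samples; %d folds need at least %d",
                 names(counts)[which.min(counts)], min(counts), folds,
                 folds))
  fold <- integer(length(labels))
  .withSeed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  acc <- vapply(sigmas, function(sg) {
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- pnnFit(X[tr, , drop = FALSE], labels[tr], sigma = sg,
                  standardize = standardize)
      pred <- pnnClassify(m, X[!tr, , drop = FALSE])$label
      hits <- hits + sum(pred == labels[!tr])
    }
    hits / length(labels)
  }, numeric(1))
  best <- sigmas[which.max(acc)]           # ties: smallest (sorted)
  attr(best, "accuracy") <- setNames(acc, sigmas)
  best
}

# ---- serialization --------------------------------------------------------

#' Save / load a PNN model as versioned flat files
#'
#' \code{writePNNModel} writes a directory holding \code{manifest.json}
#' (scalars, class names, standardisation parameters, weights) and
#' \code{centers.csv} (class column + feature columns);
#' \code{readPNNModel} restores the model.
#'
#' @param model a \linkS4class{PNNModel}.
#' @param path directory to create/use.
#' @return \code{writePNNModel}: \code{path} invisibly;
#'   \code{readPNNModel}: the restored \linkS4class{PNNModel}.
#' @export
writePNNModel <- function(model, path) {
  stopifnot(is(model, "PNNModel"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "ftirherb-pnn", version = "1.0",
                   sigma = model@sigma, classNames = model@classNames,
                   standardize = model@standardize,
                   center = model@center, scale = model@scale,
                   weights = model@weights)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  df <- data.frame(class = model@classNames[model@classIndex],
                   model@centers, check.names = FALSE)
  utils::write.csv(df, file.path(path, "centers.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writePNNModel
#' @export
readPNNModel <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$format, "ftirherb-pnn"))
    stop("not a PNN model directory: ", path)
  df <- utils::read.csv(file.path(path, "centers.csv"),
                        check.names = FALSE)
  centers <- as.matrix(df[, -1L, drop = FALSE])
  new("PNNModel", centers = centers,
      classIndex = match(df$class, manifest$classNames),
      classNames = manifest$classNames, sigma = manifest$sigma,
      weights = as.matrix(manifest$weights),
      standardize = manifest$standardize,
      center = as.numeric(manifest$center),
      scale = as.numeric(manifest$scale))
}
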