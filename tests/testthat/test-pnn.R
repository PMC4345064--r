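make3Classes <- function(nPer, spread = 0.6, seed = 77) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(3, 0), c(0, 3))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(2 * nPer, 0, spread), ncol = 2), 2L,
          centers[k, ], "+")))
  list(X = X, labels = rep(c("a", "b", "c"), each = nPer))
}

test_that("fitting stores every vector as a centre, deterministically", {
  d <- make3Classes(60)
  m <- pnnFit(d$X, d$labels, sigma = 0.5)
  expect_identical(m@classNames, c("a", "b", "c"))
  expect_identical(unname(tabulate(m@classIndex, 3L)), rep(60L, 3))
  expect_identical(nrow(m@centers), 180L)
  m2 <- pnnFit(d$X, d$labels, sigma = 0.5)
  expect_identical(m, m2)

  single <- pnnFit(rbind(c(0, 0), c(1, 1)), c("a", "b"), sigma = 1)
  expect_identical(unname(tabulate(single@classIndex, 2L)), c(1L, 1L))

  expect_error(pnnFit(d$X, d$labels, sigma = 0), "sigma")
  expect_error(pnnFit(rbind(c(1, NA), c(0, 0)), c("a", "b"), 1), "finite")
  expect_error(pnnFit(d$X, rep("a", 180), 1), "2 classes")
})

test_that("pattern responses match hand-computed kernel sums", {
  # class A centres {0, 2} on the line, sigma 1, query at 1:
  # H_A = 2 exp(-1/2)
  m <- pnnFit(matrix(c(0, 2, 10), ncol = 1), c("A", "A", "B"),
              sigma = 1, standardize = FALSE)
  H <- patternResponse(m, 1)
  expect_equal(unname(H["A"]), 2 * exp(-0.5), tolerance = 1e-9)

  # query at a class's sole centre: kernel peak, H exactly 1
  m2 <- pnnFit(rbind(c(0, 0), c(5, 5)), c("A", "B"), sigma = 0.3,
               standardize = FALSE)
  expect_identical(unname(patternResponse(m2, c(0, 0))["A"]), 1)

  # flat-kernel limit: H_k -> n_k
  d <- make3Classes(20)
  mBig <- pnnFit(d$X, d$labels, sigma = 1e6, standardize = FALSE)
  expect_equal(unname(patternResponse(mBig, c(1, 1))), rep(20, 3),
               tolerance = 1e-6)
  expect_error(patternResponse(m2, c(1, 2, 3)), "dimension")
})

test_that("classification concentrates, normalises and breaks ties by order", {
  d <- make3Classes(30)
  m <- pnnFit(d$X, d$labels, sigma = 0.3, standardize = FALSE)
  atCentre <- pnnClassify(m, d$X[31, ])     # a class-"b" training point
  expect_identical(atCentre@label, "b")
  expect_gt(atCentre@posteriors["b"], 0.99)
  expect_lt(abs(sum(atCentre@posteriors) - 1), 1e-12)

  # two single-centre classes, query equidistant: symmetric posteriors,
  # first class by order wins
  m2 <- pnnFit(rbind(c(-1, 0), c(1, 0)), c("left", "right"), sigma = 1,
               standardize = FALSE)
  tie <- pnnClassify(m2, c(0, 0))
  expect_equal(unname(tie@posteriors), c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(tie@label, "left")
})

test_that("the vanishing-bandwidth limit is 1-nearest-neighbour", {
  d <- make3Classes(15, spread = 1.5)       # overlapping clouds
  m <- pnnFit(d$X, d$labels, sigma = 1e-8, standardize = FALSE)
  set.seed(123)
  queries <- matrix(rnorm(100, 1, 2), ncol = 2)
  for (i in seq_len(nrow(queries))) {
    expect_identical(pnnClassify(m, queries[i, ])@label,
                     bruteForce1NN(d$X, d$labels, queries[i, ]))
  }
})

test_that("scores ignore training order and duplicates never hurt a class", {
  d <- make3Classes(20)
  m <- pnnFit(d$X, d$labels, sigma = 0.7, standardize = FALSE)
  perm <- sample(nrow(d$X))
  mPerm <- pnnFit(d$X[perm, ], d$labels[perm], sigma = 0.7,
                  standardize = FALSE)
  x <- c(1.2, 0.4)
  expect_equal(patternResponse(m, x)[c("a", "b", "c")],
               patternResponse(mPerm, x)[c("a", "b", "c")],
               tolerance = 1e-12)

  # duplicating a class-"a" centre adds a positive kernel term, so the
  # pooled class response cannot decrease at any query point
  dup <- rbind(d$X, d$X[1, ])
  mDup <- pnnFit(dup, c(d$labels, "a"), sigma = 0.7, standardize = FALSE)
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(2, 1, 2)
    expect_gte(patternResponse(mDup, x)["a"],
               patternResponse(m, x)["a"] - 1e-12)
  }

  # infinite-bandwidth limit: every class score ties, first class wins
  mWide <- pnnFit(d$X, d$labels, sigma = 1e12, standardize = FALSE)
  expect_identical(pnnClassify(mWide, c(50, -20))@label, "a")
})

test_that("bandwidth selection maximises CV accuracy with smallest-tie rule", {
  sep <- make3Classes(20, spread = 0.1)     # trivially separable
  s <- selectSigma(sep$X, sep$labels, sigmas = c(0.5, 1, 2), folds = 4L,
                   seed = 2L)
  expect_identical(as.numeric(s), 0.5)      # all tie at 100%: smallest

  hard <- make3Classes(30, spread = 1.0, seed = 5)
  s2 <- selectSigma(hard$X, hard$labels, sigmas = c(1e-9, 0.8, 1e9),
                    folds = 5L, seed = 3L)
  expect_identical(as.numeric(s2), 0.8)
  s3 <- selectSigma(hard$X, hard$labels, sigmas = c(1e-9, 0.8, 1e9),
                    folds = 5L, seed = 3L)
  expect_identical(attr(s2, "accuracy"), attr(s3, "accuracy"))

  expect_error(selectSigma(sep$X, sep$labels, folds = 25L), "folds")
})

test_that("models survive the flat-file round trip", {
  d <- make3Classes(12)
  m <- pnnFit(d$X, d$labels, sigma = 0.4)
  dir <- file.path(tempdir(), "pnn-roundtrip")
  writePNNModel(m, dir)
  back <- readPNNModel(dir)
  expect_identical(back@classNames, m@classNames)
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(2, 1, 1.5)
    a <- pnnClassify(m, x); b <- pnnClassify(back, x)
    expect_identical(a@label, b@label)
    expect_equal(a@posteriors, b@posteriors, tolerance = 1e-12)
  }
})
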