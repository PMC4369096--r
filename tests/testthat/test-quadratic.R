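test_that("log-determinants follow closed forms for diagonal covariances", {
  # residuals engineered so that S = I (p = 2): deviations (+-1, +-1)/sqrt(?)
  raw <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt(3 / 2)
  d <- centreAndIndex(rbind(raw, raw + 10), rep(c("a", "b"), each = 4))
  m <- fitQuadratic(d, priors = "equal")
  expect_equal(unname(classCovariances(m)[["a"]]), diag(2), tolerance = 1e-12)
  expect_equal(unname(logDeterminants(m)[["a"]]), 0, tolerance = 1e-12)

  # S = 2 I in p = 4 gives log|S| = 4 log 2
  S <- 2 * diag(4)
  ld <- 2 * sum(log(diag(chol(S))))
  expect_equal(ld, 4 * log(2), tolerance = 1e-12)
})

test_that("compound-symmetric determinant matches its closed form and the
           estimate is consistent", {
  # closed form (1 - rho)^(p-1) (1 + (p-1) rho), p = 4, rho = 0.7
  spec <- threeGroupSpec()
  S3 <- spec@covs[[3]]
  expect_equal(det(S3), (1 - 0.7)^3 * (1 + 3 * 0.7), tolerance = 1e-12)
  expect_equal(det(S3), 0.0837, tolerance = 1e-4)

  # Monte-Carlo consistency: the fitted class-3 covariance approaches S3
  big <- benchmarkFixture(seed = 5, sizes = c(4000L, 4000L, 4000L))
  m <- fitQuadratic(big)
  expect_equal(unname(classCovariances(m)[[3]]), S3, tolerance = 0.1)
  expect_equal(unname(logDeterminants(m)[[3]]), log(det(S3)),
               tolerance = 0.1)
})

test_that("priors resolve to equal, proportional or the explicit vector", {
  d <- randomFixture(n = 30, p = 2, J = 3, seed = 6)
  expect_equal(unname(classPriors(fitQuadratic(d, "equal"))), rep(1 / 3, 3))
  nj <- unname(classSizes(d))
  expect_equal(unname(classPriors(fitQuadratic(d, "proportional"))),
               nj / sum(nj))
  expect_equal(unname(classPriors(fitQuadratic(d, c(0.6, 0.3, 0.1)))),
               c(0.6, 0.3, 0.1))
  expect_error(fitQuadratic(d, c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("a class with p > n_j - 1 is reported as non-positive-definite", {
  set.seed(8)
  raw <- matrix(rnorm(5 * 4), 5, 4)              # class 'a': 2 samples, p = 4
  d <- centreAndIndex(raw, c("a", "a", "b", "b", "b"))
  expect_error(fitQuadratic(d), "positive definite")
  expect_error(fitQuadratic(d), "n_j - 1")
  # the ridge rescues it
  expect_s4_class(fitQuadratic(d, ridge = 0.5), "QuadraticModel")
})

test_that("the quadratic score matches the explicit-inverse oracle", {
  d <- randomFixture(n = 30, p = 3, J = 2, seed = 10)
  m <- fitQuadratic(d, "equal")
  X <- dataMatrix(d)
  for (j in 1:2) {
    want <- apply(X, 1, phiOracle, mean = classMeans(m)[j, ],
                  S = classCovariances(m)[[j]])
    expect_equal(phiSquared(X, m, j), unname(want), tolerance = 1e-10)
  }
  # at the class mean only the log-determinant survives
  expect_equal(phiSquared(classMeans(m)[1, ], m, 1),
               unname(logDeterminants(m)[1]), tolerance = 1e-10)
})

test_that("identity covariance reduces the score to squared Euclidean distance", {
  raw <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt(3 / 2)
  d <- centreAndIndex(rbind(raw, raw + 7), rep(c("a", "b"), each = 4))
  m <- fitQuadratic(d, "equal")
  x <- c(2, 3)
  expect_equal(phiSquared(x, m, 1),
               sum((x - classMeans(m)[1, ])^2), tolerance = 1e-10)
})

test_that("quadratic classification follows the displayed criterion", {
  d <- randomFixture(n = 45, p = 3, J = 3, seed = 12)
  m <- fitQuadratic(d, "proportional")
  X <- dataMatrix(d)
  got <- qdaClassify(X, m)
  want <- vapply(seq_len(nrow(X)), function(i) {
    phi <- vapply(1:3, function(j) phiSquared(X[i, ], m, j), numeric(1))
    discriminantOracle(phi, classPriors(m))
  }, integer(1))
  expect_equal(got, want)
  # a point at a class mean whose prior is largest goes to that class
  mp <- fitQuadratic(d, c(0.1, 0.8, 0.1))
  expect_equal(qdaClassify(classMeans(mp)[2, ], mp), 2L)
})

test_that("classification labels are invariant under orthogonal rotation", {
  d <- randomFixture(n = 40, p = 3, J = 2, seed = 13)
  m <- fitQuadratic(d, "equal")
  base <- qdaClassify(dataMatrix(d), m)
  set.seed(14)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  dr <- centreAndIndex(dataMatrix(d) %*% Q, as.character(groupLabels(d)))
  mr <- fitQuadratic(dr, "equal")
  expect_equal(qdaClassify(dataMatrix(dr), mr), base)
  # LDA labels in canonical space are likewise rotation-invariant
  cm <- suppressWarnings(canonicalTransform(scatterDecomposition(d), d, 1L))
  cmr <- suppressWarnings(canonicalTransform(scatterDecomposition(dr), dr, 1L))
  n <- nrow(dataMatrix(d))
  expect_equal(
    ldaClassify(sampleScores(cm), classMeans(cm), c(0.5, 0.5), n - 2),
    ldaClassify(sampleScores(cmr), classMeans(cmr), c(0.5, 0.5), n - 2))
})

test_that("the quadratic score grows strictly along any ray from the class mean", {
  d <- randomFixture(n = 30, p = 3, J = 2, seed = 15)
  m <- fitQuadratic(d, "equal")
  set.seed(16)
  for (rep in 1:5) {
    dir <- rnorm(3)
    ts <- seq(0, 4, by = 0.5)
    vals <- vapply(ts, function(t)
      phiSquared(classMeans(m)[1, ] + t * dir, m, 1), numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("pooled covariance collapses QDA onto LDA for every training sample", {
  d <- randomFixture(n = 60, p = 4, J = 3, seed = 17)
  mp <- fitQuadratic(d, "equal", pooled = TRUE)
  qlab <- qdaClassify(dataMatrix(d), mp)
  cm <- canonicalTransform(scatterDecomposition(d), d, r = 2L)
  n <- nrow(dataMatrix(d))
  llab <- ldaClassify(sampleScores(cm), classMeans(cm), rep(1 / 3, 3), n - 3)
  expect_equal(qlab, llab)
})

test_that("classification agrees with an independent QDA implementation", {
  d <- benchmarkFixture(seed = 21)
  m <- fitQuadratic(d, "proportional")
  ref <- MASS::qda(dataMatrix(d), grouping = groupLabels(d))
  refLab <- as.integer(predict(ref, dataMatrix(d))$class)
  expect_equal(qdaClassify(dataMatrix(d), m), refLab)
  mlda <- fitQuadratic(d, "proportional", pooled = TRUE)
  refL <- MASS::lda(dataMatrix(d), grouping = groupLabels(d))
  expect_equal(qdaClassify(dataMatrix(d), mlda),
               as.integer(predict(refL, dataMatrix(d))$class))
})
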