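test_that("the standardized score matrix honours its contract", {
  d <- benchmarkFixture()
  m <- buildPhiMatrix(d, fitQuadratic(d))
  Phi <- phiMatrix(m)
  expect_lt(max(abs(colMeans(Phi))), 1e-10)
  expect_equal(unname(apply(Phi, 2, sd)), rep(1, 3), tolerance = 1e-10)

  # raw scores reconstructed from the standardization equal the per-sample
  # oracle re-evaluation
  raw <- sweep(sweep(Phi, 2, m@phiSds, "*"), 2, m@phiMeans, "+")
  X <- dataMatrix(d)
  for (j in 1:3) {
    want <- apply(X, 1, phiOracle, mean = classMeans(m)[j, ],
                  S = classCovariances(m)[[j]])
    expect_equal(unname(raw[, j]), unname(want), tolerance = 1e-8)
  }
})

test_that("identical samples relabelled as two classes give identical raw scores", {
  set.seed(31)
  block <- matrix(rnorm(20 * 3), 20, 3)
  d <- centreAndIndex(rbind(block, block), rep(c("a", "b"), each = 20))
  m <- fitQuadratic(d, "equal")
  raw1 <- phiSquared(dataMatrix(d), m, 1)
  raw2 <- phiSquared(dataMatrix(d), m, 2)
  expect_equal(raw1, raw2, tolerance = 1e-10)
})

test_that("PCA display of the scores is orthogonal, ordered and lossless at r = J", {
  d2 <- twoGroupFixture()
  m2 <- buildPhiMatrix(d2, fitQuadratic(d2, "equal"))
  lay2 <- qdaScores(d2, m2)
  # r = J = 2: reconstruction of the standardized scores is exact
  recon <- sampleScores(lay2) %*% t(pcaLoadings(lay2))
  expect_lt(sum((phiMatrix(m2) - recon)^2), 1e-10)

  d3 <- benchmarkFixture()
  m3 <- buildPhiMatrix(d3, fitQuadratic(d3))
  lay3 <- qdaScores(d3, m3)
  sts <- crossprod(sampleScores(lay3))
  expect_lt(abs(sts[1, 2]), 1e-8 * max(diag(sts)))
  expect_gte(var(sampleScores(lay3)[, 1]), var(sampleScores(lay3)[, 2]))
  ltl <- crossprod(pcaLoadings(lay3))
  expect_lt(max(abs(ltl - diag(2))), 1e-10)
  # sign convention on loadings
  for (k in 1:2) {
    L <- pcaLoadings(lay3)[, k]
    expect_gt(L[which.max(abs(L))], 0)
  }
  expect_error(qdaScores(d3, m3, r = 4), "exceed")
})

test_that("back-projection inverts the display map", {
  d2 <- twoGroupFixture()
  m2 <- buildPhiMatrix(d2, fitQuadratic(d2, "equal"))
  lay2 <- qdaScores(d2, m2)
  raw <- sweep(sweep(phiMatrix(m2), 2, m2@phiSds, "*"), 2, m2@phiMeans, "+")
  # lossless at r = J: every sample's raw score pair is recovered
  got <- backProject(sampleScores(lay2), lay2, m2)
  expect_equal(unname(got), unname(raw), tolerance = 1e-8)
  # the display origin maps to the score column means
  expect_equal(unname(backProject(c(0, 0), lay2, m2)),
               unname(m2@phiMeans), tolerance = 1e-10)

  # J = 3: equals the rank-2 truncated-reconstruction oracle
  d3 <- benchmarkFixture()
  m3 <- buildPhiMatrix(d3, fitQuadratic(d3))
  lay3 <- qdaScores(d3, m3)
  sv <- svd(phiMatrix(m3))
  trunc <- sv$u[, 1:2] %*% diag(sv$d[1:2]) %*% t(sv$v[, 1:2])
  oracle <- sweep(sweep(trunc, 2, m3@phiSds, "*"), 2, m3@phiMeans, "+")
  got3 <- backProject(sampleScores(lay3), lay3, m3)
  expect_equal(unname(got3), unname(oracle), tolerance = 1e-8)
})

test_that("display-point classification reduces to the discriminant rule", {
  d2 <- twoGroupFixture()
  m2 <- buildPhiMatrix(d2, fitQuadratic(d2, "equal"))
  lay2 <- qdaScores(d2, m2)
  # smaller back-projected score wins under equal priors: fabricate a layout
  # point and check against the oracle on its back-projection
  z <- sampleScores(lay2)[1, ]
  phi <- backProject(z, lay2, m2)
  expect_equal(classifyDisplayPoint(z, lay2, m2),
               discriminantOracle(phi, classPriors(m2)))
  # lossless chain: display classification equals direct QDA on X
  expect_equal(classifyDisplayPoint(sampleScores(lay2), lay2, m2),
               qdaClassify(dataMatrix(d2), m2))
  # an extreme prior overrides equal scores
  m2p <- m2
  m2p@priors <- stats::setNames(c(0.99, 0.01), m2@classLabels)
  layp <- lay2
  layp@priors <- m2p@priors
  zeq <- c(0, 0)  # origin back-projects to the two column means
  phieq <- backProject(zeq, layp, m2p)
  expect_equal(classifyDisplayPoint(zeq, layp, m2p),
               discriminantOracle(phieq, c(0.99, 0.01)))
})

test_that("the region lattice covers the window and matches brute-force labels", {
  d <- benchmarkFixture()
  m <- buildPhiMatrix(d, fitQuadratic(d))
  lay <- qdaScores(d, m)
  lay2 <- buildRegionGrid(lay, m, resolution = 2L, margin = 0.1)
  expect_equal(length(regionGrid(lay2)@x) * length(regionGrid(lay2)@y), 4L)

  lay20 <- buildRegionGrid(lay, m, resolution = 20L, margin = 0.1)
  g <- regionGrid(lay20)
  pts <- cbind(rep(g@x, times = 20), rep(g@y, each = 20))
  want <- apply(pts, 1, function(z)
    discriminantOracle(backProject(z, lay, m), classPriors(m)))
  expect_equal(as.vector(g@labels), want)

  # refining the lattice never flips the label at an existing lattice point
  lay39 <- buildRegionGrid(lay, m, resolution = 39L, margin = 0.1)
  g39 <- regionGrid(lay39)
  # resolution 39 = 2*20 - 1 keeps every resolution-20 point in the lattice
  expect_equal(g39@labels[seq(1, 39, by = 2), seq(1, 39, by = 2)],
               g@labels)
})

test_that("the two-group scatter places the boundary on the identity line", {
  d <- twoGroupFixture()
  m <- buildPhiMatrix(d, fitQuadratic(d, "equal"))
  layU <- twoGroupPlot(d, m, scaled = FALSE)
  sc <- sampleScores(layU)
  lab <- classifyDisplayPoint(sc, layU, m)
  # every sample above the identity line (phi1 < phi2) is class 1
  expect_equal(lab, ifelse(sc[, 1] <= sc[, 2], 1L, 2L))
  # a point exactly on the line goes to class 1 by the tie rule
  expect_equal(classifyDisplayPoint(c(3, 3), layU, m), 1L)
  # scaled coordinates are the unscaled ones divided by the SDs
  layS <- twoGroupPlot(d, m, scaled = TRUE)
  expect_equal(sampleScores(layS),
               sweep(sc, 2, m@phiSds, "/"), tolerance = 1e-12)
  # and the scaled display classifies identically (rule uses raw scores)
  expect_equal(classifyDisplayPoint(sampleScores(layS), layS, m), lab)

  d3 <- benchmarkFixture()
  m3 <- fitQuadratic(d3)
  expect_error(twoGroupPlot(d3, buildPhiMatrix(d3, m3)), "qdaScores")
})

test_that("CVA layout scores, means and regions follow the canonical geometry", {
  d <- benchmarkFixture()
  cm <- canonicalTransform(scatterDecomposition(d), d, r = 2L)
  lay <- cvaLayout(cm, d, priors = "equal")
  # class-j samples average to the plotted class-j mean
  g <- groupLabels(d)
  for (j in 1:3)
    expect_equal(unname(colMeans(sampleScores(lay)[g == levels(g)[j], ])),
                 unname(classMeans(lay)[j, ]), tolerance = 1e-10)
  # grid labels equal the nearest-mean oracle at every lattice point
  lay <- buildRegionGrid(lay, resolution = 15L)
  gr <- regionGrid(lay)
  pts <- cbind(rep(gr@x, times = 15), rep(gr@y, each = 15))
  want <- apply(pts, 1, function(z)
    which.max(log(lay@priors) -
                0.5 * lay@ldaScale * colSums((t(classMeans(lay)) - z)^2)))
  expect_equal(as.vector(gr@labels), want)
  # equal priors: the boundary between two regions is the perpendicular
  # bisector, so each labelled point is strictly nearest its own mean
  d2 <- rowSums(pts^2) %o% rep(1, 3) -
    2 * pts %*% t(classMeans(lay)) +
    rep(1, nrow(pts)) %o% rowSums(classMeans(lay)^2)
  expect_equal(as.vector(gr@labels), max.col(-d2, ties.method = "first"))

  # two classes collapse to a rank-1 display with a warning
  d2g <- twoGroupFixture()
  cm2 <- suppressWarnings(canonicalTransform(scatterDecomposition(d2g), d2g, 2L))
  expect_warning(lay2 <- cvaLayout(cm2, d2g), "horizontal")
  expect_true(all(sampleScores(lay2)[, 2] == 0))
})

test_that("binary response patterns collapse by majority vote", {
  raw <- rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0),
               c(1, 1), c(1, 1), c(0, 1), c(0, 1))
  d <- centreAndIndex(raw, c("a", "a", "a", "b", "b", "b", "a", "b"))
  pat <- collapsePatterns(d)
  expect_equal(nrow(pat), 3L)
  p00 <- pat[pat$pattern == "00", ]
  expect_equal(p00$glyphClass, "a")            # 3 vs 1 majority
  expect_equal(p00$total, 4L)
  p01 <- pat[pat$pattern == "01", ]
  expect_equal(p01$glyphClass, "a")            # 1-1 tie -> lowest class index
  # at most 2^p patterns can occur
  set.seed(33)
  db <- pathogenPanel(40, 4, probs = c(0.5, 0.5), seed = 33)
  expect_lte(nrow(collapsePatterns(db)), 16L)
  expect_error(collapsePatterns(benchmarkFixture()), "binary")
})
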