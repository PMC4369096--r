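#' @import methods
NULL

#' Labelled multivariate data
#'
#' Container for a column-centred numeric data matrix together with the
#' per-sample group membership. Centring is on the grand mean; the removed
#' column means are retained in \code{centreOffset} so calibrated biplot axes
#' can be expressed in the original units.
#'
#' @slot X numeric matrix (n samples by p variables), column-centred.
#' @slot groups factor of length n; levels in first-appearance order.
#' @slot G 0/1 group-indicator matrix (n by J); each row sums to 1.
#' @slot classSizes integer vector of per-class counts n_j.
#' @slot centreOffset numeric vector of the column means removed by centring.
#' @slot binary logical; \code{TRUE} when every raw value was 0 or 1.
#'
#' @seealso [centreAndIndex()] which constructs validated objects.
#' @exportClass LabeledData
setClass("LabeledData",
  slots = c(
    X = "matrix",
    groups = "factor",
    G = "matrix",
    classSizes = "integer",
    centreOffset = "numeric",
    binary = "logical"
  )
)

setValidity("LabeledData", function(object) {
  msg <- character()
  n <- nrow(object@X)
  p <- ncol(object@X)
  J <- nlevels(object@groups)
  if (length(object@groups) != n)
    msg <- c(msg, "length(groups) must equal nrow(X)")
  if (J < 2)
    msg <- c(msg, "at least two classes are required")
  if (!all(dim(object@G) == c(n, J)))
    msg <- c(msg, "G must be n x J")
  if (n > 0 && J > 1 && all(dim(object@G) == c(n, J))) {
    if (any(object@G != 0 & object@G != 1))
      msg <- c(msg, "G entries must be 0 or 1")
    if (any(rowSums(object@G) != 1))
      msg <- c(msg, "each row of G must sum to 1")
    if (any(colSums(object@G) != object@classSizes))
      msg <- c(msg, "column sums of G must equal classSizes")
    if (sum(object@classSizes) != n)
      msg <- c(msg, "classSizes must sum to n")
    if (max(abs(colSums(object@X))) > 1e-10 * max(1, max(abs(object@X))))
      msg <- c(msg, "X must be column-centred")
  }
  if (length(object@centreOffset) != p)
    msg <- c(msg, "centreOffset must have one entry per variable")
  if (length(msg)) msg else TRUE
})

#' Canonical (CVA/LDA) model
#'
#' Scatter-matrix decomposition T = B + W and, once [canonicalTransform()]
#' has been applied, the canonical eigenvectors M (normalised so that
#' M'WM = I), eigenvalues, canonical sample scores and class means.
#'
#' @slot B,W,T between-, within- and total-scatter matrices (p by p).
#' @slot M canonical eigenvector matrix (p by p; at most J-1 meaningful
#'   columns).
#' @slot Lambda eigenvalues of the generalized problem, non-increasing.
#' @slot Mr first r columns of M used for the display.
#' @slot scores canonical sample scores Z = X Mr (n by r).
#' @slot classMeans class means in canonical display space (J by r).
#' @slot r display dimension used by [canonicalTransform()].
#' @slot n,J sample and class counts of the fitting data.
#' @slot classLabels class labels in first-appearance order.
#'
#' @exportClass CanonicalModel
setClass("CanonicalModel",
  slots = c(
    B = "matrix",
    W = "matrix",
    T = "matrix",
    M = "matrix",
    Lambda = "numeric",
    Mr = "matrix",
    scores = "matrix",
    classMeans = "matrix",
    r = "integer",
    n = "integer",
    J = "integer",
    classLabels = "character"
  ),
  prototype = prototype(
    M = matrix(0, 0, 0), Lambda = numeric(0), Mr = matrix(0, 0, 0),
    scores = matrix(0, 0, 0), classMeans = matrix(0, 0, 0), r = 0L
  )
)

setValidity("CanonicalModel", function(object) {
  msg <- character()
  p <- nrow(object@T)
  if (!all(dim(object@B) == c(p, p)) || !all(dim(object@W) == c(p, p)))
    msg <- c(msg, "B, W and T must be square matrices of equal size")
  rel <- max(abs(object@B + object@W - object@T)) / max(1e-300, max(abs(object@T)))
  if (rel > 1e-8)
    msg <- c(msg, "scatter decomposition violated: B + W != T")
  if (length(object@Lambda) > 1 && any(diff(object@Lambda) > 1e-8))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' Quadratic discriminant model
#'
#' Per-class means and covariances with priors, plus (after
#' [buildPhiMatrix()]) the n by J matrix of standardized quadratic scores
#' whose principal components give the QDA biplot.
#'
#' @slot classMeans J by p matrix of class mean vectors.
#' @slot classCovs list of J covariance matrices S_j (divisor n_j - 1).
#' @slot cholFactors list of upper-triangular Cholesky factors of the S_j.
#' @slot logDets log-determinants log|S_j|.
#' @slot priors class prior probabilities, summing to 1.
#' @slot Phi n by J matrix of standardized scores (mean 0, SD 1 per column);
#'   empty until [buildPhiMatrix()] is called.
#' @slot phiMeans,phiSds column means and SDs of the raw quadratic scores
#'   used for the standardization.
#' @slot classLabels class labels in first-appearance order.
#' @slot classSizes per-class sample counts of the fitting data.
#' @slot ridge ridge constant added to each covariance diagonal (default 0).
#' @slot pooled logical; \code{TRUE} when all classes share the pooled
#'   covariance estimate.
#'
#' @exportClass QuadraticModel
setClass("QuadraticModel",
  slots = c(
    classMeans = "matrix",
    classCovs = "list",
    cholFactors = "list",
    logDets = "numeric",
    priors = "numeric",
    Phi = "matrix",
    phiMeans = "numeric",
    phiSds = "numeric",
    classLabels = "character",
    classSizes = "integer",
    ridge = "numeric",
    pooled = "logical"
  ),
  prototype = prototype(
    Phi = matrix(0, 0, 0), phiMeans = numeric(0), phiSds = numeric(0),
    ridge = 0, pooled = FALSE
  )
)

setValidity("QuadraticModel", function(object) {
  msg <- character()
  J <- nrow(object@classMeans)
  if (length(object@classCovs) != J || length(object@logDets) != J)
    msg <- c(msg, "one covariance and log-determinant per class required")
  if (length(object@priors) != J)
    msg <- c(msg, "one prior per class required")
  if (any(object@priors <= 0))
    msg <- c(msg, "priors must be strictly positive")
  if (abs(sum(object@priors) - 1) > 1e-12)
    msg <- c(msg, "priors must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Calibrated biplot axis
#'
#' A variable axis fitted by the regression method: direction \code{b} in
#' display space with tick markers at round values of the variable, placed so
#' that orthogonal projection of a sample score onto the axis reads off the
#' fitted value. \code{offset} holds the orthogonal parallel translation
#' (zero until [translateAxes()] is applied); translation never changes
#' read-off values because projection is orthogonal.
#'
#' @slot variable variable name.
#' @slot direction 2-vector b (regression coefficients of the variable on the
#'   display scores).
#' @slot markers data.frame with columns \code{value}, \code{x}, \code{y}.
#' @slot offset 2-vector, orthogonal to \code{direction}.
#' @slot mean the variable's original (uncentred) mean, the read-off at the
#'   axis origin.
#'
#' @exportClass CalibratedAxis
setClass("CalibratedAxis",
  slots = c(
    variable = "character",
    direction = "numeric",
    markers = "data.frame",
    offset = "numeric",
    mean = "numeric"
  ),
  prototype = prototype(offset = c(0, 0))
)

setValidity("CalibratedAxis", function(object) {
  msg <- character()
  if (length(object@direction) != 2 || length(object@offset) != 2)
    msg <- c(msg, "direction and offset must be 2-vectors")
  if (abs(sum(object@offset * object@direction)) >
      1e-10 * max(1, sum(object@direction^2)))
    msg <- c(msg, "offset must be orthogonal to direction")
  if (nrow(object@markers) > 0) {
    pos <- cbind(object@markers$x, object@markers$y) -
      matrix(object@offset, nrow(object@markers), 2, byrow = TRUE)
    cross <- pos[, 1] * object@direction[2] - pos[, 2] * object@direction[1]
    if (max(abs(cross)) > 1e-8 * max(1, max(abs(pos))))
      msg <- c(msg, "markers must be collinear along direction")
  }
  if (length(msg)) msg else TRUE
})

#' Classification-region lattice
#'
#' Regular lattice over the display window with the predicted class at every
#' lattice point; rendered as filled regions behind the sample glyphs.
#'
#' @slot x,y lattice coordinates along each display dimension.
#' @slot labels integer matrix (length(x) by length(y)) of class indices.
#' @slot classLabels class labels the indices refer to.
#'
#' @exportClass RegionGrid
setClass("RegionGrid",
  slots = c(
    x = "numeric",
    y = "numeric",
    labels = "matrix",
    classLabels = "character"
  )
)

setValidity("RegionGrid", function(object) {
  msg <- character()
  if (!all(dim(object@labels) == c(length(object@x), length(object@y))))
    msg <- c(msg, "labels must be length(x) by length(y)")
  if (any(is.na(object@labels)))
    msg <- c(msg, "every lattice point must carry a label")
  if (length(msg)) msg else TRUE
})

#' Two-dimensional biplot layout
#'
#' Display coordinates for the samples plus everything needed to render the
#' plot: PCA loadings (QDA layout), class means (CVA layout), calibrated
#' variable axes, and the classification-region lattice. The display always
#' uses a 1:1 aspect ratio so that distances and orthogonal projections are
#' faithful.
#'
#' @slot scores n by 2 display coordinates.
#' @slot loadings J by 2 orthonormal PCA loadings (QDA layout only).
#' @slot kind "qda", "cva" or "twogroup".
#' @slot scaled for the two-group layout: whether each coordinate was divided
#'   by its standard deviation.
#' @slot axes list of [CalibratedAxis-class] objects.
#' @slot regionGrid a [RegionGrid-class], or \code{NULL} before
#'   [buildRegionGrid()].
#' @slot classMeans class means in display space (J by 2).
#' @slot priors,ldaScale classification parameters used for CVA region
#'   rendering (the scale is n - J).
#' @slot groups per-sample group factor, for plotting glyphs.
#' @slot classLabels class labels in first-appearance order.
#' @slot centreOffset the column means removed before the PCA of the
#'   standardized score matrix; identically zero by construction because the
#'   columns are standardized first (stored for the layout contract).
#'
#' @exportClass BiplotLayout
setClass("BiplotLayout",
  slots = c(
    scores = "matrix",
    loadings = "matrix",
    kind = "character",
    scaled = "logical",
    axes = "list",
    regionGrid = "ANY",
    classMeans = "matrix",
    priors = "numeric",
    ldaScale = "numeric",
    groups = "factor",
    classLabels = "character",
    centreOffset = "numeric"
  ),
  prototype = prototype(
    loadings = matrix(0, 0, 0), scaled = FALSE, axes = list(),
    regionGrid = NULL, classMeans = matrix(0, 0, 0), priors = numeric(0),
    ldaScale = 1, centreOffset = numeric(0)
  )
)

setValidity("BiplotLayout", function(object) {
  msg <- character()
  if (ncol(object@scores) != 2)
    msg <- c(msg, "scores must have 2 columns")
  if (!object@kind %in% c("qda", "cva", "twogroup"))
    msg <- c(msg, "kind must be one of 'qda', 'cva', 'twogroup'")
  if (object@kind == "qda" && ncol(object@loadings) == 2) {
    ltl <- crossprod(object@loadings)
    if (max(abs(ltl - diag(2))) > 1e-8)
      msg <- c(msg, "loadings columns must be orthonormal")
    sts <- crossprod(object@scores)
    if (abs(sts[1, 2]) > 1e-8 * max(diag(sts)))
      msg <- c(msg, "QDA display scores must be uncorrelated (PCA property)")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation specification
#'
#' Group means, covariances and sizes for the multivariate-normal benchmark
#' generator, together with the seed that makes a draw reproducible.
#'
#' @slot means J by p matrix of group mean vectors.
#' @slot covs list of J symmetric positive-definite covariance matrices.
#' @slot sizes integer vector of group sample sizes.
#' @slot seed integer RNG seed.
#'
#' @seealso [threeGroupSpec()] for the bundled three-group benchmark.
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  slots = c(
    means = "matrix",
    covs = "list",
    sizes = "integer",
    seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  J <- nrow(object@means)
  if (length(object@covs) != J || length(object@sizes) != J)
    msg <- c(msg, "one covariance matrix and one size per group required")
  if (any(object@sizes < 2L))
    msg <- c(msg, "group sizes must be at least 2")
  for (j in seq_along(object@covs)) {
    S <- object@covs[[j]]
    if (!isSymmetric(S, tol = 1e-10)) {
      msg <- c(msg, sprintf("covariance %d is not symmetric", j))
      next
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10 * max(ev))
      msg <- c(msg, sprintf("covariance %d is not positive definite", j))
  }
  if (length(msg)) msg else TRUE
})
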