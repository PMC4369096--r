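#' Fit a quadratic discriminant model
#'
#' Estimates per-class means and covariances (unbiased, divisor
#' \eqn{n_j - 1}) with log-determinants computed from a Cholesky
#' factorization; a failed factorization is reported as the
#' positive-definiteness error. Priors may be equal, proportional to class
#' size (the default, matching the usual presence/absence application), or an
#' explicit vector.
#'
#' @param data a [LabeledData-class] object.
#' @param priors \code{"proportional"} (default), \code{"equal"}, or a
#'   numeric vector of J positive values summing to 1.
#' @param ridge optional non-negative constant added to each covariance
#'   diagonal, for near-singular binary data. Default 0 (off).
#' @param pooled force every class to share the pooled within-class
#'   covariance estimate \eqn{W/(n-J)}; with equal priors the quadratic rule
#'   then coincides with LDA. Default \code{FALSE}.
#' @return a [QuadraticModel-class] (without the standardized score matrix;
#'   see [buildPhiMatrix()]).
#' @export
fitQuadratic <- function(data, priors = "proportional", ridge = 0,
                         pooled = FALSE) {
  stopifnot(is(data, "LabeledData"))
  if (ridge < 0) configError("ridge must be non-negative")
  X <- data@X
  p <- ncol(X)
  J <- nlevels(data@groups)
  nj <- data@classSizes
  lev <- levels(data@groups)
  if (any(nj < 2L))
    dataError("insufficient class size: class '%s' has fewer than 2 samples",
              lev[which(nj < 2L)[1]])
  pri <- resolvePriors(priors, nj)
  Xbar <- classMeanMatrix(data)

  covs <- vector("list", J)
  if (pooled) {
    R <- X - data@G %*% Xbar
    Sp <- crossprod(R) / (nrow(X) - J)
    for (j in seq_len(J)) covs[[j]] <- Sp
  } else {
    for (j in seq_len(J)) covs[[j]] <- stats::cov(X[data@groups == lev[j], , drop = FALSE])
  }
  chols <- vector("list", J)
  logdets <- numeric(J)
  for (j in seq_len(J)) {
    S <- covs[[j]] + ridge * diag(p)
    Rj <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(Rj))
      numericalError(paste0(
        "covariance of class '%s' is not positive definite ",
        "(is p = %d larger than n_j - 1 = %d?)"), lev[j], p, nj[j] - 1L)
    covs[[j]] <- S
    chols[[j]] <- Rj
    logdets[j] <- 2 * sum(log(diag(Rj)))
  }
  new("QuadraticModel",
      classMeans = Xbar, classCovs = covs, cholFactors = chols,
      logDets = logdets, priors = stats::setNames(pri, lev),
      classLabels = lev, classSizes = nj,
      ridge = ridge, pooled = pooled)
}

resolvePriors <- function(priors, nj) {
  J <- length(nj)
  if (is.character(priors)) {
    priors <- match.arg(priors, c("proportional", "equal"))
    if (priors == "equal") rep(1 / J, J) else nj / sum(nj)
  } else {
    priors <- as.numeric(priors)
    if (length(priors) != J)
      configError("explicit priors must have one entry per class (%d)", J)
    if (any(priors <= 0) || abs(sum(priors) - 1) > 1e-12)
      configError("explicit priors must be positive and sum to 1")
    priors
  }
}

#' Per-class quadratic discriminant score
#'
#' The score \eqn{\phi_j^2(x) = (x - \bar x_j)' S_j^{-1} (x - \bar x_j) +
#' \log|S_j|}: squared Mahalanobis distance to the class mean under that
#' class's covariance plus the covariance log-determinant. Evaluated through
#' the stored Cholesky factor; no explicit inverse is formed.
#'
#' @param x numeric p-vector, or a matrix with one sample per row, in the
#'   same (centred) coordinates as the fitting data.
#' @param model a fitted [QuadraticModel-class].
#' @param j class index (1-based, first-appearance order).
#' @return numeric score(s).
#' @export
phiSquared <- function(x, model, j) {
  stopifnot(is(model, "QuadraticModel"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  p <- ncol(model@classMeans)
  if (ncol(X) != p)
    configError("x has %d columns but the model expects %d", ncol(X), p)
  D <- sweep(X, 2, model@classMeans[j, ])
  # solve R'y = d  =>  ||y||^2 = d' S^{-1} d
  Y <- backsolve(model@cholFactors[[j]], t(D), transpose = TRUE)
  maha <- colSums(Y^2)
  unname(maha + model@logDets[j])
}

# n x J matrix of raw phi^2 scores for all samples/classes
phiScoreMatrix <- function(X, model) {
  J <- length(model@classLabels)
  out <- vapply(seq_len(J), function(j) phiSquared(X, model, j),
                numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X), ncol = J)  # vapply drops dims at n = 1
  colnames(out) <- model@classLabels
  out
}

#' Quadratic discriminant classification
#'
#' Classifies to \eqn{\arg\max_j \{\log \pi_j - \tfrac12 \phi_j^2(x)\}};
#' with equal priors this is the minimum-\eqn{\phi^2} rule. Ties are broken
#' by the lowest class index, deterministically.
#'
#' @inheritParams phiSquared
#' @return integer class index (vector for matrix input).
#' @export
qdaClassify <- function(x, model) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  phi <- phiScoreMatrix(X, model)
  crit <- sweep(-0.5 * phi, 2, log(model@priors), "+")
  max.col(crit, ties.method = "first")
}

#' @rdname QuadraticModel-class
#' @export
setMethod("classMeans", "QuadraticModel", function(object) object@classMeans)

#' @rdname QuadraticModel-class
#' @export
setMethod("classCovariances", "QuadraticModel", function(object)
  stats::setNames(object@classCovs, object@classLabels))

#' @rdname QuadraticModel-class
#' @export
setMethod("logDeterminants", "QuadraticModel", function(object)
  stats::setNames(object@logDets, object@classLabels))

#' @rdname QuadraticModel-class
#' @export
setMethod("classPriors", "QuadraticModel", function(object) object@priors)

#' @rdname QuadraticModel-class
#' @export
setMethod("phiMatrix", "QuadraticModel", function(object) {
  if (nrow(object@Phi) == 0)
    configError("standardized score matrix not built; call buildPhiMatrix() first")
  object@Phi
})

setMethod("show", "QuadraticModel", function(object) {
  cat(sprintf("QuadraticModel: %d classes, %d variables%s%s\n",
              length(object@classLabels), ncol(object@classMeans),
              if (object@pooled) " (pooled covariance)" else "",
              if (object@ridge > 0) sprintf(" (ridge %g)", object@ridge) else ""))
  cat("  priors:",
      paste(sprintf("%s=%.3f", object@classLabels, object@priors),
            collapse = ", "), "\n")
  cat("  log|S_j|:", paste(signif(object@logDets, 4), collapse = ", "), "\n")
  if (nrow(object@Phi) > 0)
    cat(sprintf("  standardized score matrix: %d x %d\n",
                nrow(object@Phi), ncol(object@Phi)))
})
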