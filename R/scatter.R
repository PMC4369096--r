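#' Between/within scatter decomposition
#'
#' Decomposes the total scatter of a centred data matrix into its
#' between-class and within-class parts, \eqn{T = B + W}. \eqn{T = X'X},
#' \eqn{W} accumulates squared deviations from the class means and
#' \eqn{B = \sum_j n_j \bar x_j \bar x_j'}; the two parts are computed
#' independently so the conservation identity is a genuine check, not a
#' tautology.
#'
#' @param data a [LabeledData-class] object.
#' @return a [CanonicalModel-class] holding \code{B}, \code{W}, \code{T}
#'   (canonical vectors are added by [canonicalTransform()]).
#' @export
scatterDecomposition <- function(data) {
  stopifnot(is(data, "LabeledData"))
  X <- data@X
  Xbar <- classMeanMatrix(data)
  R <- X - data@G %*% Xbar          # residuals from class means
  W <- crossprod(R)
  B <- crossprod(Xbar * sqrt(data@classSizes), Xbar * sqrt(data@classSizes))
  TT <- crossprod(X)
  new("CanonicalModel",
      B = B, W = W, T = TT,
      n = nrow(X), J = nlevels(data@groups),
      classLabels = levels(data@groups))
}

#' Canonical variate transformation
#'
#' Solves the generalized eigenproblem \eqn{B M = W M \Lambda} subject to
#' \eqn{M'WM = I} and attaches the leading-\code{r} canonical scores. The
#' problem is solved in whitened form: \eqn{W = R'R} (Cholesky), a symmetric
#' eigendecomposition of \eqn{R^{-T} B R^{-1}}, then \eqn{M = R^{-1} V}.
#' Each column's sign is fixed so its largest-magnitude entry is positive,
#' making the display reproducible across platforms.
#'
#' @param model a [CanonicalModel-class] from [scatterDecomposition()].
#' @param data the [LabeledData-class] the scatter was computed from.
#' @param r display dimension, 1 or 2. Values above \code{max(1, J - 1)}
#'   exceed the rank of the between-class scatter and trigger a warning.
#' @return the model with \code{M}, \code{Lambda}, \code{Mr}, canonical
#'   scores and class means filled in.
#' @export
canonicalTransform <- function(model, data, r = 2L) {
  stopifnot(is(model, "CanonicalModel"), is(data, "LabeledData"))
  r <- as.integer(r)
  if (!r %in% c(1L, 2L)) configError("display dimension r must be 1 or 2")
  J <- model@J
  if (r > max(1L, J - 1L))
    warning(sprintf(
      "r = %d exceeds the %d meaningful canonical dimension(s) for J = %d classes",
      r, max(1L, J - 1L), J))
  Rw <- tryCatch(chol(model@W), error = function(e) NULL)
  if (is.null(Rw))
    numericalError(
      "within-class scatter singular; consider regularization or variable removal")
  p <- ncol(model@W)
  Rinv <- backsolve(Rw, diag(p))
  A <- crossprod(Rinv, model@B %*% Rinv)
  A <- (A + t(A)) / 2
  eig <- eigen(A, symmetric = TRUE)
  M <- Rinv %*% eig$vectors
  # sign convention: largest-magnitude entry of each column positive
  for (k in seq_len(ncol(M))) {
    i <- which.max(abs(M[, k]))
    if (M[i, k] < 0) M[, k] <- -M[, k]
  }
  Lambda <- pmax(eig$values, 0)
  Mr <- M[, seq_len(r), drop = FALSE]
  model@M <- M
  model@Lambda <- Lambda
  model@Mr <- Mr
  model@r <- r
  model@scores <- data@X %*% Mr
  model@classMeans <- classMeanMatrix(data) %*% Mr
  validObject(model)
  model
}

#' Nearest-canonical-mean (LDA) classification
#'
#' Classifies points in canonical space to
#' \eqn{\arg\max_j \{\log \pi_j - \tfrac12 (n-J) \|u - \bar u_j\|^2\}}:
#' nearest canonical mean for equal priors, with an additive log-prior
#' adjustment otherwise. The factor \eqn{n - J} converts the W-normalised
#' canonical metric to the pooled-covariance Mahalanobis scale. Ties go to
#' the lowest class index.
#'
#' @param u numeric r-vector, or a matrix with one point per row.
#' @param classMeansU J by r matrix of class means in canonical space.
#' @param priors class priors (positive, summing to 1).
#' @param scale the multiplier of the squared distance, normally n - J.
#' @return integer class index (or vector of indices for matrix input).
#' @export
ldaClassify <- function(u, classMeansU, priors, scale) {
  U <- if (is.matrix(u)) u else matrix(u, nrow = 1)
  stopifnot(ncol(U) == ncol(classMeansU),
            length(priors) == nrow(classMeansU))
  d2 <- outer(rowSums(U^2), rowSums(classMeansU^2), "+") -
    2 * U %*% t(classMeansU)
  crit <- sweep(-0.5 * scale * d2, 2, log(priors), "+")
  max.col(crit, ties.method = "first")
}

#' @rdname CanonicalModel-class
#' @param object a \code{CanonicalModel}.
#' @export
setMethod("betweenScatter", "CanonicalModel", function(object) object@B)

#' @rdname CanonicalModel-class
#' @export
setMethod("withinScatter", "CanonicalModel", function(object) object@W)

#' @rdname CanonicalModel-class
#' @export
setMethod("totalScatter", "CanonicalModel", function(object) object@T)

#' @rdname CanonicalModel-class
#' @export
setMethod("canonicalVectors", "CanonicalModel", function(object) object@M)

#' @rdname CanonicalModel-class
#' @export
setMethod("eigenValues", "CanonicalModel", function(object) object@Lambda)

#' @rdname CanonicalModel-class
#' @export
setMethod("sampleScores", "CanonicalModel", function(object) object@scores)

#' @rdname CanonicalModel-class
#' @export
setMethod("classMeans", "CanonicalModel", function(object) object@classMeans)

setMethod("show", "CanonicalModel", function(object) {
  cat(sprintf("CanonicalModel: p = %d variables, J = %d classes\n",
              ncol(object@T), object@J))
  if (length(object@Lambda)) {
    k <- min(length(object@Lambda), object@J - 1L)
    cat("  leading eigenvalues:",
        paste(signif(object@Lambda[seq_len(max(k, 1))], 4), collapse = ", "),
        "\n")
  } else {
    cat("  canonical transform not yet computed\n")
  }
})
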