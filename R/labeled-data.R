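#' Centre a data matrix and index its group structure
#'
#' Builds a [LabeledData-class] object: the matrix is column-centred on the
#' grand mean (so \code{colSums(dataMatrix(.)) == 0}) and the group labels are
#' encoded in a 0/1 indicator matrix \code{G} whose columns follow the order
#' in which the labels first appear. The removed column means are retained so
#' biplot axes can later be calibrated in the original units.
#'
#' @param raw numeric matrix or data.frame, n samples by p variables.
#' @param labels group label per sample (n values, at least 2 distinct).
#' @param minClassSize smallest admissible class; the default 2 is what a
#'   per-class covariance estimate needs. Lower it to 1 only for pure
#'   centring/indexing uses that never reach a covariance fit.
#' @return a validated [LabeledData-class] object.
#' @examples
#' d <- centreAndIndex(matrix(c(1, 3), ncol = 1), c("a", "b"),
#'                     minClassSize = 1)
#' dataMatrix(d)      # -1, 1
#' groupIndicator(d)  # identity
#' @export
centreAndIndex <- function(raw, labels, minClassSize = 2L) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) {
    bad <- which(!vapply(seq_len(ncol(raw)),
                         function(k) all(!is.na(suppressWarnings(as.numeric(raw[, k])))),
                         logical(1)))
    badcol <- if (length(bad)) bad[1] else 1L
    badrow <- which(is.na(suppressWarnings(as.numeric(raw[, badcol]))))[1]
    dataError("non-numeric value at row %d, column %d (%s)",
              badrow, badcol,
              colnames(raw)[badcol] %||% as.character(badcol))
  }
  if (anyNA(raw)) {
    idx <- which(is.na(raw), arr.ind = TRUE)[1, ]
    dataError("missing value at row %d, column %d; no imputation is performed",
              idx[1], idx[2])
  }
  n <- nrow(raw)
  p <- ncol(raw)
  if (p < 1) dataError("at least one variable is required")
  if (anyNA(labels) || length(labels) != n)
    dataError("labels must be non-missing, one per sample")
  groups <- factor(as.character(labels), levels = unique(as.character(labels)))
  J <- nlevels(groups)
  if (J < 2) dataError("at least two classes are required")
  if (n < J) dataError("need at least one sample per class")
  nj <- as.integer(table(groups))
  if (any(nj < minClassSize)) {
    small <- levels(groups)[which(nj < minClassSize)[1]]
    dataError("insufficient class size: class '%s' has fewer than %d samples",
              small, minClassSize)
  }
  offset <- colMeans(raw)
  X <- sweep(raw, 2, offset)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  G <- matrix(0, n, J, dimnames = list(NULL, levels(groups)))
  G[cbind(seq_len(n), as.integer(groups))] <- 1
  new("LabeledData",
      X = X, groups = groups, G = G, classSizes = nj,
      centreOffset = stats::setNames(offset, colnames(X)),
      binary = all(raw %in% c(0, 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname LabeledData-class
#' @export
setMethod("dataMatrix", "LabeledData", function(object) object@X)

#' @rdname LabeledData-class
#' @export
setMethod("groupLabels", "LabeledData", function(object) object@groups)

#' @rdname LabeledData-class
#' @export
setMethod("groupIndicator", "LabeledData", function(object) object@G)

#' @rdname LabeledData-class
#' @export
setMethod("classSizes", "LabeledData", function(object)
  stats::setNames(object@classSizes, levels(object@groups)))

#' @rdname LabeledData-class
#' @export
setMethod("centreOffset", "LabeledData", function(object) object@centreOffset)

# per-class mean matrix (J x p) of the centred data
classMeanMatrix <- function(data) {
  Xbar <- crossprod(data@G, data@X) / data@classSizes
  rownames(Xbar) <- levels(data@groups)
  Xbar
}

#' @rdname LabeledData-class
#' @export
setMethod("classMeans", "LabeledData", function(object) classMeanMatrix(object))

setMethod("show", "LabeledData", function(object) {
  cat(sprintf("LabeledData: %d samples, %d variables, %d classes%s\n",
              nrow(object@X), ncol(object@X), nlevels(object@groups),
              if (object@binary) " (binary 0/1)" else ""))
  cat("  class sizes:",
      paste(sprintf("%s=%d", levels(object@groups), object@classSizes),
            collapse = ", "), "\n")
})
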