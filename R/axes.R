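#' Calibrated variable axes by the regression method
#'
#' Fits each variable to the display by least squares: the axis direction is
#' \eqn{b_k = (Z'Z)^{-1} Z' x_k} with \eqn{x_k} the centred variable column,
#' so the fitted value of a sample score \eqn{z} is \eqn{z'b_k + \bar x_k}.
#' Calibration markers are placed at round values \eqn{v} (1-2-5 rule over
#' the observed range; 0 and 1 only for binary variables) at position
#' \eqn{((v - \bar x_k)/\|b_k\|^2)\, b_k}, so orthogonal projection of a
#' score onto the axis reads off its fitted value. Axes pass through the
#' display origin until [translateAxes()] is applied.
#'
#' @param layout a [BiplotLayout-class] with scores built.
#' @param data the fitting [LabeledData-class].
#' @param whichVariables variable names or indices to fit (default all).
#' @return list of [CalibratedAxis-class] objects; variables whose direction
#'   is numerically zero are omitted with a warning.
#' @export
regressionAxes <- function(layout, data, whichVariables = NULL) {
  stopifnot(is(layout, "BiplotLayout"), is(data, "LabeledData"))
  X <- data@X
  vars <- colnames(X)
  if (is.null(whichVariables)) whichVariables <- vars
  if (is.numeric(whichVariables)) whichVariables <- vars[whichVariables]
  if (!all(whichVariables %in% vars))
    configError("unknown variable(s): %s",
                paste(setdiff(whichVariables, vars), collapse = ", "))
  Z <- layout@scores
  qrZ <- qr(Z)                       # tolerates rank-1 score matrices
  axes <- list()
  for (k in whichVariables) {
    xk <- X[, k]
    b <- qr.coef(qrZ, xk)
    b[is.na(b)] <- 0
    b <- unname(b)
    if (sqrt(sum(b^2)) < 1e-12) {
      warning(sprintf("axis for '%s' is degenerate (zero direction); omitted", k))
      next
    }
    mk <- data@centreOffset[[k]]
    origVals <- xk + mk
    vals <- markerValues(origVals, binary = all(origVals %in% c(0, 1)))
    pos <- outer((vals - mk) / sum(b^2), b)
    axes[[k]] <- new("CalibratedAxis",
                     variable = k, direction = b,
                     markers = data.frame(value = vals,
                                          x = pos[, 1], y = pos[, 2]),
                     offset = c(0, 0), mean = mk)
  }
  axes
}

# round calibration values: base R's pretty() implements the 1-2-5 rule
markerValues <- function(values, binary = FALSE) {
  if (binary) return(c(0, 1))
  v <- pretty(range(values), n = 5)
  v[v >= min(values) - 1e-12 & v <= max(values) + 1e-12]
}

#' Read calibrated values off an axis
#'
#' Orthogonally projects display scores onto an axis and returns the
#' calibrated (fitted) values, \eqn{(z - \mathrm{offset})' b + \bar x_k}.
#' Because the offset is orthogonal to the direction, translated and
#' untranslated axes read off identical values.
#'
#' @param z display point(s): 2-vector or matrix with one point per row.
#' @param axis a [CalibratedAxis-class].
#' @return numeric fitted value(s) in the variable's original units.
#' @export
axisReadOff <- function(z, axis) {
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 2)
  drop((Z - matrix(axis@offset, nrow(Z), 2, byrow = TRUE)) %*%
         axis@direction + axis@mean)
}

#' Orthogonal parallel translation of biplot axes
#'
#' Shifts each axis perpendicular to its direction so its drawn line clears
#' the cloud of sample scores, leaving read-off values unchanged (projection
#' is orthogonal, and the shift has no component along the axis). Each axis
#' moves just beyond the convex hull of the scores on whichever side of the
#' axis line is nearer, deterministically given the scores.
#'
#' @param axes list of [CalibratedAxis-class] objects.
#' @param layout the [BiplotLayout-class] providing the sample scores.
#' @param strategy \code{"hull-clear"} (default) or \code{"none"} (leave all
#'   axes through the origin).
#' @param pad clearance beyond the hull, as a fraction of the orthogonal
#'   score spread (default 0.05).
#' @return the axes with their \code{offset} slots set.
#' @export
translateAxes <- function(axes, layout, strategy = c("hull-clear", "none"),
                          pad = 0.05) {
  strategy <- match.arg(strategy)
  lapply(axes, function(ax) {
    if (strategy == "none") {
      ax@offset <- c(0, 0)
      return(ax)
    }
    d <- ax@direction / sqrt(sum(ax@direction^2))
    o <- c(-d[2], d[1])                       # unit normal
    proj <- drop(layout@scores %*% o)
    lo <- min(proj); hi <- max(proj)
    gap <- pad * max(hi - lo, 1e-8)
    shift <- if (abs(hi) <= abs(lo)) hi + gap else lo - gap
    ax@offset <- shift * o
    ax@markers$x <- ax@markers$x + ax@offset[1]
    ax@markers$y <- ax@markers$y + ax@offset[2]
    validObject(ax)
    ax
  })
}
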