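#' Build the standardized quadratic-score matrix
#'
#' Evaluates the raw per-class scores \eqn{\phi_j^2(x_i)} for every sample
#' and class, then standardizes each of the J columns to mean 0 and unit
#' standard deviation (sample SD, divisor n - 1). These J "new" variables
#' form the matrix whose principal components give the QDA biplot; the
#' column means and SDs are retained for back-projection to raw scores.
#'
#' @param data the [LabeledData-class] the model was fitted to.
#' @param model a fitted [QuadraticModel-class].
#' @return the model with \code{Phi}, \code{phiMeans} and \code{phiSds}
#'   filled in.
#' @export
buildPhiMatrix <- function(data, model) {
  stopifnot(is(data, "LabeledData"), is(model, "QuadraticModel"))
  raw <- phiScoreMatrix(data@X, model)
  mns <- colMeans(raw)
  sds <- apply(raw, 2, stats::sd)
  if (any(sds < 1e-12))
    numericalError(paste0(
      "quadratic score column for class '%s' has zero variance; ",
      "all samples are equidistant from that class and the standardized ",
      "display is degenerate"),
      model@classLabels[which(sds < 1e-12)[1]])
  model@Phi <- sweep(sweep(raw, 2, mns), 2, sds, "/")
  model@phiMeans <- mns
  model@phiSds <- sds
  model
}

#' QDA biplot coordinates by PCA of the standardized scores
#'
#' Principal component analysis of the n by J standardized score matrix.
#' The columns already have mean zero by construction, so no re-centring is
#' applied (the stored centre offset is identically zero). Samples are
#' represented by the first \code{r} principal component scores; loadings are
#' the corresponding right singular vectors, with each component's sign fixed
#' so its largest-magnitude loading is positive. For J = 2 groups the r = 2
#' representation is exact.
#'
#' @param data the fitting [LabeledData-class] (provides group glyphs).
#' @param model a [QuadraticModel-class] with the score matrix built.
#' @param r number of display dimensions, at most J. Default 2.
#' @return a [BiplotLayout-class] of kind \code{"qda"}.
#' @export
qdaScores <- function(data, model, r = 2L) {
  stopifnot(is(model, "QuadraticModel"))
  Phi <- phiMatrix(model)
  J <- ncol(Phi)
  r <- as.integer(r)
  if (r > J)
    configError("r = %d display dimensions exceed the %d score columns", r, J)
  sv <- svd(Phi, nu = r, nv = r)
  scores <- sv$u %*% diag(sv$d[seq_len(r)], r)
  loadings <- sv$v
  for (k in seq_len(r)) {
    i <- which.max(abs(loadings[, k]))
    if (loadings[i, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(loadings) <- model@classLabels
  G <- data@G
  classMeans2d <- crossprod(G, scores) / data@classSizes
  new("BiplotLayout",
      scores = scores, loadings = loadings, kind = "qda",
      classMeans = classMeans2d,
      priors = model@priors, groups = data@groups,
      classLabels = model@classLabels,
      centreOffset = rep(0, J))
}

#' Back-project a display point to raw quadratic scores
#'
#' Maps a 2-D display point back to the J-vector of approximate per-class
#' scores \eqn{\hat\phi_j^2}: the PCA loadings reconstruct the standardized
#' scores (\code{loadings \%*\% z}; the columns have mean zero so no centring
#' term enters), then each entry is un-standardized with the stored column SD
#' and mean. For the two-group scatter layout the display coordinates are the
#' raw (or SD-scaled) scores themselves and the map is the identity (or the
#' SD rescaling). Exact for J = 2 QDA layouts, where r = J makes the
#' projection lossless.
#'
#' @param z numeric 2-vector, or a matrix of display points (one per row).
#' @param layout a [BiplotLayout-class].
#' @param model the [QuadraticModel-class] behind the layout.
#' @return numeric J-vector of raw scores, or an n by J matrix.
#' @export
backProject <- function(z, layout, model) {
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 2)
  raw <- switch(layout@kind,
    qda = {
      std <- Z %*% t(layout@loadings)
      sweep(sweep(std, 2, model@phiSds, "*"), 2, model@phiMeans, "+")
    },
    twogroup = {
      if (layout@scaled) sweep(Z, 2, model@phiSds[1:2], "*") else Z
    },
    configError("back-projection is defined for 'qda' and 'twogroup' layouts"))
  colnames(raw) <- model@classLabels
  if (is.matrix(z)) raw else drop(raw)
}

#' Classify a display point through back-projection
#'
#' Applies the discriminant rule
#' \eqn{\arg\max_j \{\log \pi_j - \tfrac12 \hat\phi_j^2(z)\}} to the
#' back-projected raw scores of a display point; with equal priors this is
#' the minimum-\eqn{\hat\phi^2} rule. Ties go to the lowest class index. For
#' CVA layouts the point is classified to the nearest canonical class mean
#' with the log-prior adjustment instead.
#'
#' @inheritParams backProject
#' @return integer class index (vector for matrix input).
#' @export
classifyDisplayPoint <- function(z, layout, model = NULL) {
  Z <- if (is.matrix(z)) z else matrix(z, ncol = 2)
  if (layout@kind == "cva")
    return(ldaClassify(Z, layout@classMeans, layout@priors, layout@ldaScale))
  stopifnot(is(model, "QuadraticModel"))
  phi <- backProject(Z, layout, model)
  if (!is.matrix(phi)) phi <- matrix(phi, nrow = 1)
  crit <- sweep(-0.5 * phi, 2, log(layout@priors), "+")
  max.col(crit, ties.method = "first")
}

#' Rasterize the classification regions
#'
#' Lays a regular lattice over the display window (the score range extended
#' by a margin on each side) and classifies every lattice point with
#' [classifyDisplayPoint()]; the labelled lattice is drawn as filled regions
#' behind the sample glyphs.
#'
#' @param layout a [BiplotLayout-class].
#' @param model the model behind the layout ([QuadraticModel-class]; ignored
#'   for CVA layouts).
#' @param resolution lattice points per side (default 400).
#' @param margin fraction of the score range added on each side (default 0.1).
#' @return the layout with its \code{regionGrid} slot filled.
#' @export
buildRegionGrid <- function(layout, model = NULL, resolution = 400L,
                            margin = 0.1) {
  resolution <- as.integer(resolution)
  if (resolution < 2L) configError("resolution must be at least 2")
  rng <- apply(layout@scores, 2, range)
  span <- rng[2, ] - rng[1, ]
  # a rank-1 display (e.g. CVA with two classes) gets a window borrowed
  # from the non-degenerate dimension
  span[span < 1e-8] <- max(span, 1e-8) / 2
  lo <- rng[1, ] - margin * span
  hi <- rng[2, ] + margin * span
  gx <- seq(lo[1], hi[1], length.out = resolution)
  gy <- seq(lo[2], hi[2], length.out = resolution)
  pts <- cbind(rep(gx, times = resolution), rep(gy, each = resolution))
  lab <- classifyDisplayPoint(pts, layout, model)
  grid <- new("RegionGrid", x = gx, y = gy,
              labels = matrix(lab, nrow = resolution),
              classLabels = layout@classLabels)
  layout@regionGrid <- grid
  layout
}

#' Two-group quadratic score scatter
#'
#' For J = 2 groups the natural display plots \eqn{\phi_2^2(x)} against
#' \eqn{\phi_1^2(x)} directly: with equal priors the classification boundary
#' is literally the line y = x (class 1 where \eqn{\phi_1^2 < \phi_2^2}).
#' Because one group is often far more concentrated than the other, the
#' default divides each coordinate by its standard deviation; region labels
#' are always computed from the raw scores, so the rule is unchanged.
#'
#' @param data the fitting [LabeledData-class].
#' @param model a fitted two-class [QuadraticModel-class] (the score matrix
#'   is built on the fly if absent).
#' @param scaled divide each coordinate by its SD? Default \code{TRUE}.
#' @return a [BiplotLayout-class] of kind \code{"twogroup"}.
#' @export
twoGroupPlot <- function(data, model, scaled = TRUE) {
  stopifnot(is(data, "LabeledData"), is(model, "QuadraticModel"))
  if (length(model@classLabels) != 2)
    configError(
      "the two-group scatter needs exactly 2 classes; use qdaScores() for J > 2")
  if (nrow(model@Phi) == 0) model <- buildPhiMatrix(data, model)
  raw <- sweep(sweep(model@Phi, 2, model@phiSds, "*"), 2, model@phiMeans, "+")
  scores <- if (scaled) sweep(raw, 2, model@phiSds, "/") else raw
  classMeans2d <- crossprod(data@G, scores) / data@classSizes
  new("BiplotLayout",
      scores = unname(scores), kind = "twogroup", scaled = scaled,
      classMeans = unname(classMeans2d),
      priors = model@priors, groups = data@groups,
      classLabels = model@classLabels,
      centreOffset = rep(0, 2))
}

#' Canonical variate (CVA/LDA) biplot layout
#'
#' Sample scores Z = X Mr with the class means overlaid; classification
#' regions are rendered by the nearest-canonical-mean rule with the
#' log-prior adjustment and scale n - J. For J = 2 classes only one
#' canonical dimension is meaningful: a warning is issued and the rank-1
#' scores are plotted along the horizontal axis.
#'
#' @param canonical a [CanonicalModel-class] with the transform computed at
#'   r = 2.
#' @param data the fitting [LabeledData-class].
#' @param priors \code{"proportional"}, \code{"equal"}, or explicit vector.
#' @return a [BiplotLayout-class] of kind \code{"cva"}.
#' @export
cvaLayout <- function(canonical, data, priors = "proportional") {
  stopifnot(is(canonical, "CanonicalModel"), is(data, "LabeledData"))
  if (canonical@r < 1L)
    configError("run canonicalTransform() before building the CVA layout")
  pri <- resolvePriors(priors, data@classSizes)
  J <- canonical@J
  scores <- canonical@scores
  cm <- canonical@classMeans
  if (J == 2 && ncol(dataMatrix(data)) >= 2) {
    warning(paste(
      "two classes give a single meaningful canonical dimension;",
      "plotting rank-1 scores on the horizontal axis"))
    scores <- cbind(scores[, 1], 0)
    cm <- cbind(cm[, 1], 0)
  } else if (ncol(scores) == 1) {
    scores <- cbind(scores[, 1], 0)
    cm <- cbind(cm[, 1], 0)
  }
  new("BiplotLayout",
      scores = scores, kind = "cva",
      classMeans = cm,
      priors = stats::setNames(pri, canonical@classLabels),
      ldaScale = canonical@n - J,
      groups = data@groups,
      classLabels = canonical@classLabels,
      centreOffset = rep(0, 2))
}

#' Collapse identical binary response patterns
#'
#' With p binary variables at most 2^p distinct response patterns exist, so
#' identical patterns share one point in the display. Each unique pattern is
#' summarised with its per-class counts; the displayed class is the majority
#' vote (ties to the lowest class index) and glyphs may be scaled by
#' multiplicity.
#'
#' @param data a binary [LabeledData-class].
#' @return data.frame with one row per distinct pattern: the pattern string,
#'   one count column per class, \code{total}, and \code{glyphClass}.
#' @export
collapsePatterns <- function(data) {
  stopifnot(is(data, "LabeledData"))
  if (!data@binary)
    configError("pattern collapsing requires binary 0/1 data")
  raw <- sweep(data@X, 2, -data@centreOffset)  # undo centring
  key <- apply(round(raw), 1, paste, collapse = "")
  tab <- table(key, data@groups)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  glyph <- max.col(counts, ties.method = "first")
  out <- data.frame(pattern = rownames(counts), counts,
                    total = rowSums(counts),
                    glyphClass = colnames(counts)[glyph],
                    row.names = NULL, check.names = FALSE)
  out[order(-out$total, out$pattern), , drop = FALSE]
}

#' @rdname BiplotLayout-class
#' @export
setMethod("sampleScores", "BiplotLayout", function(object) object@scores)

#' @rdname BiplotLayout-class
#' @export
setMethod("classMeans", "BiplotLayout", function(object) object@classMeans)

#' @rdname BiplotLayout-class
#' @export
setMethod("layoutKind", "BiplotLayout", function(object) object@kind)

#' @rdname BiplotLayout-class
#' @export
setMethod("biplotAxes", "BiplotLayout", function(object) object@axes)

#' @rdname BiplotLayout-class
#' @export
setMethod("regionGrid", "BiplotLayout", function(object) object@regionGrid)

#' @rdname BiplotLayout-class
#' @export
setMethod("pcaLoadings", "BiplotLayout", function(object) object@loadings)

setMethod("show", "BiplotLayout", function(object) {
  cat(sprintf("BiplotLayout (%s): %d samples, %d classes\n",
              object@kind, nrow(object@scores), length(object@classLabels)))
  if (length(object@axes))
    cat(sprintf("  %d calibrated axes\n", length(object@axes)))
  if (!is.null(object@regionGrid))
    cat(sprintf("  region grid %d x %d\n",
                length(object@regionGrid@x), length(object@regionGrid@y)))
})

setMethod("show", "CalibratedAxis", function(object) {
  cat(sprintf("CalibratedAxis '%s': direction (%.3g, %.3g), %d markers%s\n",
              object@variable, object@direction[1], object@direction[2],
              nrow(object@markers),
              if (any(object@offset != 0)) ", translated" else ""))
})

setMethod("show", "RegionGrid", function(object) {
  cat(sprintf("RegionGrid: %d x %d lattice, classes: %s\n",
              length(object@x), length(object@y),
              paste(object@classLabels, collapse = ", ")))
})
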