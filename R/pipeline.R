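#' Fit, lay out and render a discriminant biplot in one call
#'
#' End-to-end pipeline: read the data, centre and index it, fit the
#' requested model (QDA, CVA, or the two-group quadratic-score scatter),
#' build the display with calibrated axes and classification regions,
#' render the plot, and write the per-sample predicted labels and the
#' resubstitution confusion matrix. Every resolved default is logged.
#'
#' @param input path to a delimited input file, or a [LabeledData-class]
#'   object directly.
#' @param groupCol group column name or index (for file input).
#' @param kind display kind: \code{"qda"} (default), \code{"cva"} or
#'   \code{"twogroup"}.
#' @param priors \code{"proportional"} (default), \code{"equal"} or an
#'   explicit vector.
#' @param resolution,margin region-lattice resolution and window margin.
#' @param axisVariables variables to draw as calibrated axes (default all).
#' @param translation axis translation strategy, \code{"hull-clear"} or
#'   \code{"none"}.
#' @param scaled for \code{kind = "twogroup"}: SD-scale the coordinates?
#' @param ridge optional covariance ridge (see [fitQuadratic()]).
#' @param plotFile,layoutFile,labelsFile,confusionFile,regionFile optional
#'   output paths; each output is written only when its path is given.
#' @param sep field separator for file input.
#' @param verbose log one line per pipeline stage (default \code{TRUE}).
#' @return invisibly, a list with the \code{data}, \code{model},
#'   \code{layout}, predicted \code{labels} and \code{confusion} matrix.
#' @export
runFitPlot <- function(input, groupCol = "group",
                       kind = c("qda", "cva", "twogroup"),
                       priors = "proportional",
                       resolution = 400L, margin = 0.1,
                       axisVariables = NULL,
                       translation = c("hull-clear", "none"),
                       scaled = TRUE, ridge = 0,
                       plotFile = NULL, layoutFile = NULL,
                       labelsFile = NULL, confusionFile = NULL,
                       regionFile = NULL, sep = ",", verbose = TRUE) {
  kind <- match.arg(kind)
  translation <- match.arg(translation)
  data <- if (is(input, "LabeledData")) input
          else readLabeledData(input, groupCol, sep)
  J <- nlevels(groupLabels(data))
  stageLog("read", sprintf("n=%d p=%d J=%d", nrow(dataMatrix(data)),
                           ncol(dataMatrix(data)), J), verbose = verbose)
  if (kind == "twogroup" && J != 2)
    configError(
      "the two-group display needs exactly 2 classes (found %d); use kind='qda'",
      J)

  if (kind == "cva") {
    canon <- canonicalTransform(scatterDecomposition(data), data, r = 2L)
    dev <- max(abs(crossprod(canon@M, canon@W %*% canon@M) -
                     diag(ncol(canon@W))))
    stageLog("fit-cva", sprintf("max|M'WM - I|=%.2e lambda1=%.4g",
                                dev, canon@Lambda[1]), verbose = verbose)
    layout <- withCallingHandlers(
      cvaLayout(canon, data, priors),
      warning = function(w) {
        stageLog("fit-cva", conditionMessage(w), verbose = verbose)
        invokeRestart("muffleWarning")
      })
    model <- NULL
    pred <- ldaClassify(layout@scores, layout@classMeans, layout@priors,
                        layout@ldaScale)
  } else {
    model <- fitQuadratic(data, priors, ridge = ridge)
    model <- buildPhiMatrix(data, model)
    stageLog("fit-qda", sprintf("priors=%s logdets=%s",
                                paste(signif(model@priors, 3), collapse = "/"),
                                paste(signif(model@logDets, 3), collapse = "/")),
             verbose = verbose)
    layout <- if (kind == "twogroup") twoGroupPlot(data, model, scaled)
              else qdaScores(data, model, r = 2L)
    pred <- qdaClassify(dataMatrix(data), model)
  }
  stageLog("layout", sprintf("kind=%s", kind), verbose = verbose)

  layout@axes <- translateAxes(
    regressionAxes(layout, data, axisVariables), layout, translation)
  stageLog("axes", sprintf("%d axes, translation=%s",
                           length(layout@axes), translation),
           verbose = verbose)
  layout <- buildRegionGrid(layout, model, resolution, margin)
  stageLog("regions", sprintf("resolution=%d margin=%g", resolution, margin),
           verbose = verbose)

  lev <- layout@classLabels
  predLab <- factor(lev[pred], levels = lev)
  confusion <- table(observed = groupLabels(data), predicted = predLab)

  if (!is.null(plotFile)) {
    renderBiplot(layout, plotFile,
                 collapseBinary = data@binary, data = data)
    stageLog("render", plotFile, verbose = verbose)
  }
  if (!is.null(layoutFile)) exportLayoutJSON(layout, layoutFile)
  if (!is.null(regionFile)) exportRegionGrid(layout@regionGrid, regionFile)
  if (!is.null(labelsFile))
    utils::write.csv(data.frame(sample = seq_along(pred),
                                observed = as.character(groupLabels(data)),
                                predicted = as.character(predLab)),
                     labelsFile, row.names = FALSE, quote = FALSE)
  if (!is.null(confusionFile))
    utils::write.csv(as.data.frame.matrix(confusion), confusionFile,
                     quote = FALSE)
  invisible(list(data = data, model = model, layout = layout,
                 labels = predLab, confusion = confusion))
}

#' Simulate a benchmark data set and write it as CSV
#'
#' Draws the three-group multivariate-normal benchmark (see
#' [threeGroupSpec()]), optionally dichotomized at the pooled medians into
#' 0/1 indicators, writes it as a CSV matching the [readLabeledData()]
#' contract, and records the seed in a JSON sidecar.
#'
#' @param out output CSV path.
#' @param sizes per-group sample sizes (default 50 each).
#' @param seed RNG seed (default 42, the bundled-fixture seed).
#' @param dichotomize write the median-dichotomized indicator version?
#' @param verbose log resolved parameters.
#' @return invisibly, the simulated [LabeledData-class].
#' @export
runSimulate <- function(out, sizes = c(50L, 50L, 50L), seed = 42L,
                        dichotomize = FALSE, verbose = TRUE) {
  sizes <- as.integer(sizes)
  if (any(is.na(sizes)) || any(sizes < 2L))
    configError("group sizes must be integers >= 2")
  spec <- threeGroupSpec(sizes = sizes, seed = as.integer(seed))
  data <- simulateNormal(spec)
  if (dichotomize) data <- dichotomizeAtMedian(data)
  writeLabeledCSV(data, out)
  meta <- list(seed = spec@seed, sizes = spec@sizes,
               dichotomized = dichotomize,
               generator = paste0("R ", getRversion(), " Mersenne-Twister"))
  jsonlite::write_json(meta, paste0(out, ".meta.json"), auto_unbox = TRUE)
  stageLog("simulate", sprintf("n=%s seed=%d dichotomize=%s -> %s",
                               paste(sizes, collapse = "/"), seed,
                               dichotomize, out), verbose = verbose)
  invisible(data)
}
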