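#' Read labelled data from delimited text
#'
#' Reads a CSV/TSV file with a header row, one row per sample, one column
#' per variable and one group-label column, then centres and indexes it with
#' [centreAndIndex()]. Missing values are an error; no imputation is
#' performed.
#'
#' @param path file path.
#' @param groupCol group column, by name or 1-based index. Default
#'   \code{"group"}.
#' @param sep field separator (\code{","} default; use \code{"\t"} for TSV).
#' @return a [LabeledData-class].
#' @export
readLabeledData <- function(path, groupCol = "group", sep = ",") {
  if (!file.exists(path)) dataError("input file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.numeric(groupCol)) {
    if (groupCol < 1 || groupCol > ncol(df))
      configError("group column index %d out of range", groupCol)
    gidx <- as.integer(groupCol)
  } else {
    gidx <- match(groupCol, colnames(df))
    if (is.na(gidx))
      configError("group column '%s' not found (columns: %s)", groupCol,
                  paste(colnames(df), collapse = ", "))
  }
  labels <- df[[gidx]]
  vars <- df[, -gidx, drop = FALSE]
  for (k in seq_along(vars)) {
    if (!is.numeric(vars[[k]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vars[[k]]))) &
                     !is.na(vars[[k]]))[1]
      dataError("non-numeric value in column '%s', row %d",
                colnames(vars)[k], if (is.na(bad)) 1L else bad)
    }
  }
  centreAndIndex(as.matrix(vars), labels)
}

#' Write labelled data as CSV
#'
#' Writes the original (uncentred) values with full \code{\%.17g} precision
#' so that a write-then-read round trip reproduces every double exactly,
#' plus the group-label column.
#'
#' @param data a [LabeledData-class].
#' @param path output file path.
#' @param groupCol name for the group column (default \code{"group"}).
#' @return \code{path}, invisibly.
#' @export
writeLabeledCSV <- function(data, path, groupCol = "group") {
  stopifnot(is(data, "LabeledData"))
  raw <- sweep(data@X, 2, -data@centreOffset)
  vals <- apply(raw, c(1, 2), function(v) sprintf("%.17g", v))
  # binary data round-trips more readably as integers
  if (data@binary) vals <- apply(round(raw), c(1, 2), function(v) sprintf("%d", as.integer(v)))
  lines <- c(paste(c(colnames(raw), groupCol), collapse = ","),
             paste(apply(vals, 1, paste, collapse = ","),
                   as.character(data@groups), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Export a biplot layout as JSON
#'
#' Serialises scores, loadings, class means, calibrated axes (direction,
#' offset, markers) and, when present, the classification-region lattice, so
#' downstream tooling can re-render the display without refitting.
#'
#' @param layout a [BiplotLayout-class].
#' @param path output file path.
#' @param digits passed to [jsonlite::write_json()] (default \code{NA}: full
#'   precision).
#' @return \code{path}, invisibly.
#' @export
exportLayoutJSON <- function(layout, path, digits = NA) {
  stopifnot(is(layout, "BiplotLayout"))
  axes <- lapply(layout@axes, function(ax) list(
    variable = ax@variable,
    direction = ax@direction,
    offset = ax@offset,
    mean = ax@mean,
    markers = ax@markers))
  obj <- list(
    kind = layout@kind,
    scaled = layout@scaled,
    scores = unname(layout@scores),
    loadings = unname(layout@loadings),
    classMeans = unname(layout@classMeans),
    classLabels = layout@classLabels,
    priors = unname(layout@priors),
    groups = as.character(layout@groups),
    axes = unname(axes))
  if (!is.null(layout@regionGrid))
    obj$regionGrid <- list(x = layout@regionGrid@x,
                           y = layout@regionGrid@y,
                           labels = unname(layout@regionGrid@labels))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = digits)
  invisible(path)
}

#' Rebuild a biplot layout from its JSON export
#'
#' Inverse of [exportLayoutJSON()]: reconstructs a [BiplotLayout-class]
#' (scores, loadings, class means, axes with markers, region lattice) so a
#' plot can be re-rendered without refitting. A layout exported at full
#' precision re-renders identically to the fresh fit.
#'
#' @param path path to a JSON file written by [exportLayoutJSON()].
#' @return a [BiplotLayout-class].
#' @export
layoutFromJSON <- function(path) {
  if (!file.exists(path)) dataError("layout file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  asMat <- function(rows, ncol = NULL) {
    if (length(rows) == 0) return(matrix(0, 0, ncol %||% 0))
    do.call(rbind, lapply(rows, function(r) unlist(r, use.names = FALSE)))
  }
  axes <- lapply(obj$axes, function(a) {
    mk <- a$markers
    new("CalibratedAxis",
        variable = a$variable,
        direction = unlist(a$direction),
        offset = unlist(a$offset),
        mean = a$mean,
        markers = data.frame(value = vapply(mk, `[[`, 0, "value"),
                             x = vapply(mk, `[[`, 0, "x"),
                             y = vapply(mk, `[[`, 0, "y")))
  })
  names(axes) <- vapply(obj$axes, `[[`, "", "variable")
  classLabels <- unlist(obj$classLabels)
  grid <- NULL
  if (!is.null(obj$regionGrid))
    grid <- new("RegionGrid",
                x = unlist(obj$regionGrid$x),
                y = unlist(obj$regionGrid$y),
                labels = asMat(obj$regionGrid$labels),
                classLabels = classLabels)
  new("BiplotLayout",
      scores = asMat(obj$scores, 2),
      loadings = asMat(obj$loadings, 2),
      kind = obj$kind,
      scaled = isTRUE(obj$scaled),
      axes = axes,
      regionGrid = grid,
      classMeans = asMat(obj$classMeans, 2),
      priors = unlist(obj$priors),
      groups = factor(unlist(obj$groups), levels = classLabels),
      classLabels = classLabels,
      centreOffset = rep(0, 2))
}

#' Export the classification-region lattice as a delimited table
#'
#' One row per lattice point with columns \code{x}, \code{y}, \code{label}.
#'
#' @param grid a [RegionGrid-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
exportRegionGrid <- function(grid, path) {
  stopifnot(is(grid, "RegionGrid"))
  df <- data.frame(
    x = rep(grid@x, times = length(grid@y)),
    y = rep(grid@y, each = length(grid@x)),
    label = grid@classLabels[as.vector(grid@labels)])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
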