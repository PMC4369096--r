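#' Draw a biplot layout
#'
#' Renders the classification regions (when built) as filled background
#' tiles, the sample glyphs coloured by group, the class means, and any
#' calibrated axes with their tick markers. The device aspect ratio is fixed
#' at 1:1 so distances and orthogonal projections on screen are faithful to
#' the display geometry. For binary data, identical response patterns are
#' collapsed to one glyph whose class is the majority vote and whose size
#' grows with multiplicity.
#'
#' @param x a [BiplotLayout-class].
#' @param y ignored.
#' @param main plot title.
#' @param palette one colour per class (defaults to a colour-blind-safe set).
#' @param collapseBinary collapse identical binary patterns into single
#'   majority-vote glyphs (needs \code{data}).
#' @param data the fitting [LabeledData-class]; only used when
#'   \code{collapseBinary = TRUE}.
#' @param ... further arguments passed to [graphics::plot()].
#' @return invisibly, \code{x}.
#' @export
setMethod("plot", signature(x = "BiplotLayout", y = "missing"),
  function(x, y, main = NULL, palette = NULL, collapseBinary = FALSE,
           data = NULL, ...) {
  layout <- x
  J <- length(layout@classLabels)
  if (is.null(palette))
    palette <- rep(c("#E69F00", "#56B4E9", "#009E73", "#CC79A7",
                     "#0072B2", "#D55E00"), length.out = J)
  fill <- grDevices::adjustcolor(palette, alpha.f = 0.25)
  sc <- layout@scores
  grid <- layout@regionGrid
  xlim <- if (!is.null(grid)) range(grid@x) else range(sc[, 1])
  ylim <- if (!is.null(grid)) range(grid@y) else range(sc[, 2])
  graphics::plot(NA, xlim = xlim, ylim = ylim, asp = 1,
                 xlab = displayAxisLabel(layout, 1),
                 ylab = displayAxisLabel(layout, 2),
                 main = main %||% sprintf("%s biplot", toupper(layout@kind)),
                 ...)
  if (!is.null(grid))
    graphics::image(grid@x, grid@y, grid@labels,
                    col = fill, zlim = c(1, J) + c(-0.5, 0.5),
                    add = TRUE, useRaster = TRUE)
  if (layout@kind == "twogroup" && !layout@scaled)
    graphics::abline(0, 1, lty = 2, col = "grey40")
  gi <- as.integer(layout@groups)
  if (collapseBinary && !is.null(data) && data@binary) {
    pat <- collapsePatterns(data)
    key <- apply(round(sweep(data@X, 2, -data@centreOffset)), 1,
                 paste, collapse = "")
    first <- !duplicated(key)
    m <- match(key[first], pat$pattern)
    graphics::points(sc[first, 1], sc[first, 2],
                     col = palette[match(pat$glyphClass[m],
                                         layout@classLabels)],
                     pch = 19, cex = 0.7 + 0.3 * log1p(pat$total[m]))
  } else {
    graphics::points(sc[, 1], sc[, 2], col = palette[gi],
                     pch = c(19, 17, 15, 18, 3, 4)[(gi - 1) %% 6 + 1],
                     cex = 0.8)
  }
  if (nrow(layout@classMeans) == J)
    graphics::points(layout@classMeans[, 1], layout@classMeans[, 2],
                     pch = 21, bg = palette, col = "black", cex = 1.6)
  for (ax in layout@axes) drawAxis(ax, xlim, ylim)
  graphics::legend("topright", legend = layout@classLabels,
                   col = palette, pch = 19, bty = "n", cex = 0.9)
  invisible(x)
})

displayAxisLabel <- function(layout, which) {
  switch(layout@kind,
    qda = sprintf("PC%d of standardized quadratic scores", which),
    cva = sprintf("canonical variate %d", which),
    twogroup = {
      lab <- sprintf("phi^2 (%s)", layout@classLabels[which])
      if (layout@scaled) paste(lab, "/ SD") else lab
    })
}

# draw one calibrated axis: the line through offset along direction, clipped
# to the plot window, with tick markers and value labels
drawAxis <- function(ax, xlim, ylim) {
  d <- ax@direction / sqrt(sum(ax@direction^2))
  ts <- c((xlim - ax@offset[1]) / ifelse(d[1] == 0, NA, d[1]),
          (ylim - ax@offset[2]) / ifelse(d[2] == 0, NA, d[2]))
  ts <- range(ts[is.finite(ts)])
  ends <- rbind(ax@offset + ts[1] * d, ax@offset + ts[2] * d)
  graphics::lines(ends[, 1], ends[, 2], col = "grey30")
  graphics::points(ax@markers$x, ax@markers$y, pch = 3, cex = 0.5,
                   col = "grey30")
  graphics::text(ax@markers$x, ax@markers$y,
                 labels = format(ax@markers$value), pos = 3, cex = 0.6,
                 col = "grey30")
  lab_end <- ends[which.max(ends[, 1] * d[1] + ends[, 2] * d[2]), ]
  graphics::text(lab_end[1], lab_end[2], ax@variable, cex = 0.8, font = 3)
}

#' Render a biplot layout to an image file
#'
#' Opens a device chosen by file extension (\code{.svg}, \code{.png} or
#' \code{.pdf}), draws the layout with [plot()] and closes the device.
#'
#' @inheritParams exportLayoutJSON
#' @param file output path; the extension selects the device.
#' @param width,height device size in inches (pixels/96 for PNG).
#' @param ... passed on to the plot method.
#' @return \code{file}, invisibly.
#' @export
renderBiplot <- function(layout, file, width = 7, height = 7, ...) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    svg = grDevices::svg(file, width = width, height = height),
    png = grDevices::png(file, width = 96 * width, height = 96 * height,
                         res = 96),
    pdf = grDevices::pdf(file, width = width, height = height),
    configError("unsupported plot format '.%s' (use svg, png or pdf)", ext))
  on.exit(grDevices::dev.off())
  plot(layout, ...)
  invisible(file)
}
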