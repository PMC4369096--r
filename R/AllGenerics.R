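#' @rdname LabeledData-class
#' @param object an object.
#' @export
setGeneric("dataMatrix", function(object) standardGeneric("dataMatrix"))

#' @rdname LabeledData-class
#' @export
setGeneric("groupLabels", function(object) standardGeneric("groupLabels"))

#' @rdname LabeledData-class
#' @export
setGeneric("groupIndicator", function(object) standardGeneric("groupIndicator"))

#' @rdname LabeledData-class
#' @export
setGeneric("classSizes", function(object) standardGeneric("classSizes"))

#' @rdname LabeledData-class
#' @export
setGeneric("centreOffset", function(object) standardGeneric("centreOffset"))

#' @rdname CanonicalModel-class
#' @export
setGeneric("betweenScatter", function(object) standardGeneric("betweenScatter"))

#' @rdname CanonicalModel-class
#' @export
setGeneric("withinScatter", function(object) standardGeneric("withinScatter"))

#' @rdname CanonicalModel-class
#' @export
setGeneric("totalScatter", function(object) standardGeneric("totalScatter"))

#' @rdname CanonicalModel-class
#' @export
setGeneric("canonicalVectors", function(object) standardGeneric("canonicalVectors"))

#' @rdname CanonicalModel-class
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))

#' Display-space sample scores
#'
#' @param object a [CanonicalModel-class] or [BiplotLayout-class].
#' @return numeric matrix of 2-D (or r-D) sample coordinates.
#' @export
setGeneric("sampleScores", function(object) standardGeneric("sampleScores"))

#' Class means of a fitted model or layout
#'
#' @param object a fitted model or layout object.
#' @export
setGeneric("classMeans", function(object) standardGeneric("classMeans"))

#' @rdname QuadraticModel-class
#' @param object a \code{QuadraticModel}.
#' @export
setGeneric("classCovariances", function(object) standardGeneric("classCovariances"))

#' @rdname QuadraticModel-class
#' @export
setGeneric("logDeterminants", function(object) standardGeneric("logDeterminants"))

#' @rdname QuadraticModel-class
#' @export
setGeneric("classPriors", function(object) standardGeneric("classPriors"))

#' @rdname QuadraticModel-class
#' @export
setGeneric("phiMatrix", function(object) standardGeneric("phiMatrix"))

#' @rdname BiplotLayout-class
#' @param object a \code{BiplotLayout}.
#' @export
setGeneric("layoutKind", function(object) standardGeneric("layoutKind"))

#' @rdname BiplotLayout-class
#' @export
setGeneric("biplotAxes", function(object) standardGeneric("biplotAxes"))

#' @rdname BiplotLayout-class
#' @export
setGeneric("regionGrid", function(object) standardGeneric("regionGrid"))

#' @rdname BiplotLayout-class
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))
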