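#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `genes()` returns
#' the ordered gene identifiers, `subjects()` the ordered subject
#' identifiers, `edgeWeights()` the symmetric weight matrix of a
#' [GeneNetwork], `operatorMatrix()` the row-stochastic matrix of a
#' [NormalizedOperator], `burdenEncoding()` and `orientation()` the encoding
#' and per-gene orientation metadata of a [BurdenMatrix], and
#' `selectionProbability()`, `maxProbability()`, `selectedGenes()` and
#' `lambdaValues()` the components of a [StabilityResult].
#'
#' @param x an object of the matching class.
#' @return The slot value; see each class's documentation.
#' @name accessors
#' @aliases genes subjects edgeWeights operatorMatrix burdenEncoding
#'   orientation selectionProbability maxProbability selectedGenes
#'   lambdaValues
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("isBinary", function(x) standardGeneric("isBinary"))

#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname accessors
#' @export
setGeneric("operatorMatrix", function(x) standardGeneric("operatorMatrix"))

#' @rdname accessors
#' @export
setGeneric("burdenEncoding", function(x) standardGeneric("burdenEncoding"))

#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname accessors
#' @export
setGeneric("selectionProbability",
  function(x) standardGeneric("selectionProbability"))

#' @rdname accessors
#' @export
setGeneric("maxProbability", function(x) standardGeneric("maxProbability"))

#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname accessors
#' @export
setGeneric("lambdaValues", function(x) standardGeneric("lambdaValues"))

#' @rdname accessors
#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))

#' @rdname accessors
#' @export
setGeneric("finalDelta", function(x) standardGeneric("finalDelta"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))
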