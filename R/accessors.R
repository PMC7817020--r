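#' @rdname accessors
#' @export
setMethod("genes", "GeneNetwork", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("genes", "NormalizedOperator", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("genes", "BurdenMatrix", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("genes", "SmoothedScores", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("genes", "StabilityResult", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("subjects", "BurdenMatrix", function(x) x@subjects)

#' @rdname accessors
#' @export
setMethod("subjects", "SmoothedScores", function(x) x@subjects)

#' @rdname accessors
#' @export
setMethod("edgeWeights", "GeneNetwork", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("isBinary", "GeneNetwork", function(x) x@isBinary)

#' @rdname accessors
#' @export
setMethod("numEdges", "GeneNetwork", function(x) {
  w <- x@weights
  offdiag <- Matrix::nnzero(w) - sum(Matrix::diag(w) != 0)
  as.integer(offdiag / 2 + sum(Matrix::diag(w) != 0))
})

#' @rdname accessors
#' @export
setMethod("operatorMatrix", "NormalizedOperator", function(x) x@operator)

#' @rdname accessors
#' @export
setMethod("burdenEncoding", "BurdenMatrix", function(x) x@encoding)

#' @rdname accessors
#' @export
setMethod("orientation", "BurdenMatrix", function(x) x@orientation)

#' @rdname accessors
#' @export
setMethod("selectionProbability", "StabilityResult",
  function(x) x@selectionProbability)

#' @rdname accessors
#' @export
setMethod("maxProbability", "StabilityResult", function(x) x@maxProbability)

#' @rdname accessors
#' @export
setMethod("selectedGenes", "StabilityResult", function(x) x@selected)

#' @rdname accessors
#' @export
setMethod("lambdaValues", "StabilityResult", function(x) x@lambda)

#' @rdname accessors
#' @export
setMethod("iterations", "SmoothedScores", function(x) x@iterations)

#' @rdname accessors
#' @export
setMethod("finalDelta", "SmoothedScores", function(x) x@finalDelta)

#' @rdname accessors
#' @export
setMethod("converged", "SmoothedScores", function(x) x@converged)

#' Extract the numeric matrix from a container
#'
#' @param x a [BurdenMatrix] (returns a sparse-backed base matrix) or
#'   [SmoothedScores] (returns the dense score matrix), subjects in rows,
#'   genes in columns.
#' @param ... ignored.
#' @return a base `matrix` with subject/gene dimnames.
#' @export
setMethod("as.matrix", "BurdenMatrix", function(x, ...) {
  m <- as.matrix(x@values)
  dimnames(m) <- list(x@subjects, x@genes)
  m
})

#' @rdname as.matrix-BurdenMatrix-method
#' @export
setMethod("as.matrix", "SmoothedScores", function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@subjects, x@genes)
  m
})

setMethod("dim", "BurdenMatrix", function(x) dim(x@values))
setMethod("dim", "SmoothedScores", function(x) dim(x@values))

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf(
    "GeneNetwork: %d genes, %d edges (%s%s)\n",
    length(object@genes), numEdges(object),
    if (object@isBinary) "binary adjacency" else "weighted",
    if (object@allowSelfLoops) ", self-loops allowed" else ""
  ))
})

setMethod("show", "NormalizedOperator", function(object) {
  iso <- sum(Matrix::rowSums(object@operator) == 0)
  cat(sprintf(
    "NormalizedOperator: %d genes, row-stochastic (%d isolated)\n",
    length(object@genes), iso
  ))
})

setMethod("show", "BurdenMatrix", function(object) {
  cat(sprintf(
    "BurdenMatrix: %d subjects x %d genes, encoding '%s'%s\n",
    length(object@subjects), length(object@genes), object@encoding,
    if (nrow(object@orientation)) ", effect-oriented" else ""
  ))
  dens <- Matrix::nnzero(object@values) / max(1, length(object@values))
  cat(sprintf("  nonzero density: %.4f\n", dens))
})

setMethod("show", "SmoothedScores", function(object) {
  cat(sprintf(
    "SmoothedScores: %d subjects x %d genes (alpha = %g)\n",
    length(object@subjects), length(object@genes), object@alpha
  ))
  cat(sprintf(
    "  %d iterations, final delta %.3g%s\n",
    object@iterations, object@finalDelta,
    if (object@converged) "" else " [NOT CONVERGED]"
  ))
})

setMethod("show", "StabilityResult", function(object) {
  cat(sprintf(
    "StabilityResult: %d genes x %d lambda values, %d %s resamples\n",
    length(object@genes), length(object@lambda), object@nResamples,
    object@counting
  ))
  cat(sprintf(
    "  %d gene(s) with selection probability >= %.2f",
    length(object@selected), object@threshold
  ))
  if (length(object@selected)) {
    cat(": ", paste(utils::head(object@selected, 8), collapse = ", "))
    if (length(object@selected) > 8) cat(", ...")
  }
  cat("\n")
})

setMethod("show", "SimulationSpec", function(object) {
  topo <- if (is.null(object@network)) {
    sprintf("star2 (hub + %d + %d)", object@n1, object@n2)
  } else {
    sprintf("supplied network (hub %s)", object@hub)
  }
  cat(sprintf(
    "SimulationSpec: %d cases / %d controls, scenario %d, %s\n",
    object@nCases, object@nControls, object@scenario, topo
  ))
  cat(sprintf(
    "  f_case = %g, f_control = %g, alpha = %g, %d reps, seed %g\n",
    object@fCase, object@fControl, object@alpha, object@nReps, object@seed
  ))
})
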