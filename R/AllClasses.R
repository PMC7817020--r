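#' @import methods
#' @importClassesFrom Matrix Matrix
NULL

setClassUnion("matrixOrMatrix", c("matrix", "Matrix"))
setClassUnion("GeneNetworkOrNULL", "NULL")

#' GeneNetwork: a weighted, undirected gene-interaction graph
#'
#' Holds an ordered set of gene identifiers and a symmetric M x M weight
#' matrix with entries in \[0, 1\]. Edge weights express the probabilistic
#' evidence of a functional interaction between two genes (tissue-specific
#' networks of this form are typically distributed as three-column edge
#' lists). A binarized network (`isBinary = TRUE`) is the adjacency matrix
#' obtained by keeping only the top-weighted edges; see
#' [binarizeTopEdges()].
#'
#' @slot genes character vector of unique gene identifiers (length M).
#' @slot weights symmetric M x M sparse [Matrix::Matrix] with entries in
#'   \[0, 1\]; the diagonal is zero unless `allowSelfLoops`.
#' @slot isBinary logical; `TRUE` after binarization (all weights 0/1).
#' @slot allowSelfLoops logical; whether diagonal entries are permitted.
#'
#' @seealso [loadNetwork()], [degreeNormalize()],
#'   [randomizePreservingDegree()], [geneNeighbourhood()]
#' @export
setClass("GeneNetwork",
  slots = c(
    genes = "character",
    weights = "Matrix",
    isBinary = "logical",
    allowSelfLoops = "logical"
  )
)

setValidity("GeneNetwork", function(object) {
  msg <- character()
  w <- object@weights
  m <- length(object@genes)
  if (anyDuplicated(object@genes)) {
    msg <- c(msg, "duplicate gene identifiers")
  }
  if (nrow(w) != m || ncol(w) != m) {
    msg <- c(msg, sprintf("weights must be %d x %d", m, m))
  } else {
    if (!Matrix::isSymmetric(w, tol = 0)) {
      msg <- c(msg, "weights matrix must be exactly symmetric")
    }
    x <- w@x
    if (length(x) && (min(x) < 0 || max(x) > 1)) {
      msg <- c(msg, "edge weights must lie in [0, 1]")
    }
    if (isTRUE(object@isBinary) && length(x) && !all(x %in% c(0, 1))) {
      msg <- c(msg, "binary network must have weights in {0, 1}")
    }
    if (!isTRUE(object@allowSelfLoops) && any(Matrix::diag(w) != 0)) {
      msg <- c(msg, "diagonal must be zero when self-loops are disallowed")
    }
  }
  if (length(msg)) msg else TRUE
})

#' NormalizedOperator: the row-stochastic diffusion operator D %*% N
#'
#' The propagation operator obtained by dividing every row of a network's
#' weight matrix N by the corresponding node strength (row sum), i.e. the
#' product of N with the diagonal matrix D of inverse node strengths.
#' Rows of isolated genes (strength zero) are left all-zero so that gene
#' indices stay aligned with the burden matrix.
#'
#' @slot genes gene order inherited from the source [GeneNetwork].
#' @slot operator M x M sparse matrix; every nonzero row sums to 1.
#'
#' @seealso [degreeNormalize()], [propagateBurden()]
#' @export
setClass("NormalizedOperator",
  slots = c(
    genes = "character",
    operator = "Matrix"
  )
)

setValidity("NormalizedOperator", function(object) {
  msg <- character()
  w <- object@operator
  m <- length(object@genes)
  if (nrow(w) != m || ncol(w) != m) {
    msg <- c(msg, sprintf("operator must be %d x %d", m, m))
  } else {
    if (length(w@x) && min(w@x) < 0) {
      msg <- c(msg, "operator entries must be nonnegative")
    }
    rs <- Matrix::rowSums(w)
    bad <- abs(rs - 1) > 1e-12 & rs != 0
    if (any(bad)) {
      msg <- c(msg, sprintf(
        "%d row(s) neither sum to 1 (tol 1e-12) nor are all-zero", sum(bad)
      ))
    }
  }
  if (length(msg)) msg else TRUE
})

#' BurdenMatrix: subject x gene rare-variant burden
#'
#' The sparse matrix G0 of per-subject, per-gene rare-variant signal fed
#' into network propagation. Three encodings are supported:
#' * `status`: 0/1, gene carries at least one qualifying variant;
#' * `burden`: nonnegative integer count of qualifying variants;
#' * `signed_status`: -1/0/+1, status signed by direction of effect
#'   (risk +1, protective -1; see [orientEffects()]).
#'
#' @slot subjects ordered subject identifiers (length S).
#' @slot genes ordered gene identifiers (length M), aligned to the
#'   companion [GeneNetwork]'s gene order.
#' @slot values S x M sparse matrix.
#' @slot encoding one of `"status"`, `"burden"`, `"signed_status"`.
#' @slot orientation per-gene orientation metadata (`data.frame`; empty
#'   until [orientEffects()] is applied). Columns: gene, the four 2x2
#'   contingency counts, oddsRatio, direction.
#'
#' @seealso [buildBurden()], [orientEffects()], [propagateBurden()]
#' @export
setClass("BurdenMatrix",
  slots = c(
    subjects = "character",
    genes = "character",
    values = "Matrix",
    encoding = "character",
    orientation = "data.frame"
  ),
  prototype = prototype(orientation = data.frame())
)

setValidity("BurdenMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != length(object@subjects) || ncol(v) != length(object@genes)) {
    msg <- c(msg, "values dimensions must match subjects x genes")
  }
  if (anyDuplicated(object@subjects)) msg <- c(msg, "duplicate subject ids")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene ids")
  enc <- object@encoding
  if (length(enc) != 1 || !enc %in% c("status", "burden", "signed_status")) {
    msg <- c(msg, "encoding must be one of status, burden, signed_status")
  } else {
    x <- v@x
    ok <- switch(enc,
      status = all(x %in% c(0, 1)),
      burden = all(x >= 0 & x == round(x)),
      signed_status = all(x %in% c(-1, 0, 1))
    )
    if (!ok) msg <- c(msg, sprintf("values incompatible with encoding '%s'", enc))
  }
  if (length(msg)) msg else TRUE
})

#' SmoothedScores: subject x gene scores after network propagation
#'
#' Dense result of iterating the propagation update until the Frobenius
#' norm of the iterate difference drops below the convergence threshold.
#' A gene's smoothed score blends its own rare-variant signal with signal
#' diffusing in from its network neighbourhood.
#'
#' @slot subjects,genes identifiers aligned with the input [BurdenMatrix].
#' @slot values S x M numeric matrix of smoothed scores.
#' @slot iterations number of update steps performed.
#' @slot finalDelta Frobenius norm of the last iterate difference.
#' @slot converged `FALSE` iff the iteration cap was hit before the
#'   threshold was reached.
#' @slot alpha diffusion length used.
#' @slot tol convergence threshold used.
#'
#' @seealso [propagateBurden()], [closedFormPropagate()],
#'   [quantileNormalizeRows()]
#' @export
setClass("SmoothedScores",
  slots = c(
    subjects = "character",
    genes = "character",
    values = "matrix",
    iterations = "numeric",
    finalDelta = "numeric",
    converged = "logical",
    alpha = "numeric",
    tol = "numeric"
  )
)

setValidity("SmoothedScores", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != length(object@subjects) || ncol(v) != length(object@genes)) {
    msg <- c(msg, "values dimensions must match subjects x genes")
  }
  if (!all(is.finite(v))) msg <- c(msg, "all smoothed scores must be finite")
  if (length(msg)) msg else TRUE
})

#' StabilityResult: selection probabilities from stability selection
#'
#' Per-gene selection probabilities across the sparsity (lambda) path of an
#' L1-penalized logistic regression, estimated over repeated class-stratified
#' split-half resamples; genes whose maximal probability reaches the
#' threshold form the selected set.
#'
#' @slot genes gene identifiers (length M).
#' @slot lambda strictly decreasing sparsity path (length L).
#' @slot selectionProbability M x L matrix of selection probabilities.
#' @slot maxProbability named per-gene maximum over the path.
#' @slot selected genes with `maxProbability >= threshold`.
#' @slot threshold selection-probability cutoff (default 0.80).
#' @slot nResamples number of resamples.
#' @slot counting `"plain"` (one half per resample) or `"complementary"`
#'   (both halves; probability granularity 1/(2 nResamples)).
#' @slot seed RNG seed used (NA if none supplied).
#'
#' @seealso [stabilitySelect()], [stabilityPaths()]
#' @export
setClass("StabilityResult",
  slots = c(
    genes = "character",
    lambda = "numeric",
    selectionProbability = "matrix",
    maxProbability = "numeric",
    selected = "character",
    threshold = "numeric",
    nResamples = "numeric",
    counting = "character",
    seed = "numeric"
  )
)

setValidity("StabilityResult", function(object) {
  msg <- character()
  p <- object@selectionProbability
  if (nrow(p) != length(object@genes) || ncol(p) != length(object@lambda)) {
    msg <- c(msg, "selectionProbability must be genes x lambda")
  }
  if (length(p) && (min(p) < 0 || max(p) > 1)) {
    msg <- c(msg, "probabilities must lie in [0, 1]")
  }
  if (any(diff(object@lambda) >= 0)) {
    msg <- c(msg, "lambda path must be strictly decreasing")
  }
  if (!setequal(
    object@selected,
    object@genes[object@maxProbability >= object@threshold]
  )) {
    msg <- c(msg, "selected set inconsistent with maxProbability/threshold")
  }
  if (length(msg)) msg else TRUE
})

#' SimulationSpec: planted-signal cohort simulation settings
#'
#' Describes a synthetic case/control cohort with differential SNV carrier
#' frequencies planted in the network neighbourhood of an unmutated hub
#' gene. Three mutation scenarios are supported: 1 = only first neighbours
#' of the hub mutated, 2 = only second neighbours, 3 = both tiers; the hub
#' itself is never mutated.
#'
#' @slot nCases,nControls cohort sizes.
#' @slot fCase,fControl per-gene carrier probabilities in mutated tiers
#'   for cases and controls.
#' @slot scenario 1, 2 or 3 (see above).
#' @slot n1,n2 first/second-ring sizes of the default two-tier star
#'   topology (used when no network is supplied).
#' @slot alpha,topPct,quantileNormalize propagation settings for sweeps.
#' @slot nReps replicates per parameter cell.
#' @slot seed base RNG seed.
#' @slot network optional [GeneNetwork] to use instead of the star fixture.
#' @slot hub hub gene identifier (required with a supplied network).
#'
#' @seealso [simulationSpec()], [simulateCohort()], [parameterSweep()]
#' @export
setClass("SimulationSpec",
  slots = c(
    nCases = "numeric",
    nControls = "numeric",
    fCase = "numeric",
    fControl = "numeric",
    scenario = "numeric",
    n1 = "numeric",
    n2 = "numeric",
    alpha = "numeric",
    topPct = "numeric",
    quantileNormalize = "logical",
    nReps = "numeric",
    seed = "numeric",
    network = "ANY",
    hub = "character"
  )
)

setValidity("SimulationSpec", function(object) {
  msg <- character()
  if (object@nCases < 1 || object@nControls < 1) {
    msg <- c(msg, "cohort sizes must be >= 1")
  }
  for (f in c(object@fCase, object@fControl)) {
    if (f < 0 || f > 1) msg <- c(msg, "carrier frequencies must lie in [0, 1]")
  }
  if (!object@scenario %in% 1:3) msg <- c(msg, "scenario must be 1, 2 or 3")
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "alpha must lie in [0, 1]")
  if (!is.null(object@network)) {
    if (!is(object@network, "GeneNetwork")) {
      msg <- c(msg, "network must be a GeneNetwork or NULL")
    } else if (!length(object@hub) || !object@hub %in% object@network@genes) {
      msg <- c(msg, "hub gene must exist in the supplied network")
    }
  } else if (object@n1 < 1 || object@n2 < 0) {
    msg <- c(msg, "star topology needs n1 >= 1 and n2 >= 0")
  }
  if (length(msg)) msg else TRUE
})
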