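#' Propagate rare-variant burdens over the network
#'
#' Iterates the diffusion update
#' \deqn{G^{t+1} = \alpha\, G^t (D N) + (1 - \alpha)\, G^0}
#' starting from the burden matrix `G0`, where `D N` is the row-stochastic
#' operator from [degreeNormalize()] and `alpha` is the diffusion length:
#' `alpha = 0` performs no propagation (the result is `G0`, returned
#' bit-identically), while values near 1 let signal travel far from its
#' source. Iteration stops when the Frobenius norm of the whole iterate
#' difference falls below `tol`; for `alpha < 1` the update is a
#' contraction, so convergence is guaranteed. If `maxIters` is reached
#' first, the result carries `converged = FALSE` and a warning is raised —
#' an unconverged matrix is never returned silently.
#'
#' The update right-multiplies by the operator: mass held by gene `j` in a
#' subject's row is redistributed along row `j` of `D N`, i.e. pushed to
#' the genes `j` points at, in proportion to edge weight over node
#' strength. Negated inputs propagate to negated outputs (the operator is
#' linear), which is what makes signed risk/protective encodings
#' meaningful.
#'
#' Dense or sparse arithmetic is chosen automatically from the burden's
#' density (`method = "auto"`); both paths implement the same update and
#' agree to ~1e-10.
#'
#' @param burden a [BurdenMatrix] (or plain subject x gene matrix) whose
#'   gene order is identical to the operator's.
#' @param op a [NormalizedOperator] from [degreeNormalize()].
#' @param alpha diffusion length in \[0, 1\]; default 0.5.
#' @param tol convergence threshold on the Frobenius norm of the iterate
#'   difference; default 1e-6.
#' @param maxIters iteration cap; default 1000.
#' @param quantileNormalize apply [quantileNormalizeRows()] to the
#'   converged scores (off by default; row-wise quantile normalization
#'   tends to erode case/control differences in the hub score).
#' @param method `"auto"`, `"dense"` or `"sparse"` arithmetic.
#' @return a [SmoothedScores].
#' @seealso [closedFormPropagate()] for the exact fixed point.
#' @export
propagateBurden <- function(burden, op, alpha = 0.5, tol = 1e-6,
                            maxIters = 1000, quantileNormalize = FALSE,
                            method = c("auto", "dense", "sparse")) {
  method <- match.arg(method)
  stopifnot(is(op, "NormalizedOperator"))
  if (is(burden, "BurdenMatrix")) {
    g0 <- burden@values
    subjectIds <- burden@subjects
    geneIds <- burden@genes
  } else {
    g0 <- burden
    subjectIds <- rownames(burden) %||% paste0("S", seq_len(nrow(burden)))
    geneIds <- colnames(burden) %||% op@genes
  }
  if (!identical(as.character(geneIds), op@genes)) {
    stop("burden gene order must be identical to the operator's gene order")
  }
  if (anyNA(g0)) stop("burden contains missing values")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  if (tol <= 0) stop("tol must be > 0")
  if (maxIters < 1) stop("maxIters must be >= 1")
  if (alpha == 1 && !is.finite(maxIters)) {
    stop("alpha = 1 requires a finite maxIters")
  }

  if (alpha == 0) {
    vals <- as.matrix(g0)
    dimnames(vals) <- list(subjectIds, geneIds)
    out <- new("SmoothedScores",
      subjects = as.character(subjectIds), genes = as.character(geneIds),
      values = vals, iterations = 1, finalDelta = 0, converged = TRUE,
      alpha = alpha, tol = tol
    )
    if (quantileNormalize) out <- quantileNormalizeRows(out)
    return(out)
  }

  density <- Matrix::nnzero(asSparse(g0)) / max(1, length(g0))
  useSparse <- switch(method,
    auto = density < 0.05,
    dense = FALSE,
    sparse = TRUE
  )
  w <- op@operator
  g0w <- if (useSparse) asSparse(g0) else as.matrix(g0)
  g <- g0w
  it <- 0
  delta <- Inf
  while (it < maxIters) {
    gNext <- alpha * (g %*% w) + (1 - alpha) * g0w
    it <- it + 1
    delta <- frobenius(gNext - g)
    g <- gNext
    if (delta < tol) break
  }
  conv <- delta < tol
  if (!conv) {
    warning(sprintf(
      "propagation did not converge in %d iterations (delta = %.3g)",
      maxIters, delta
    ))
  }
  vals <- as.matrix(g)
  dimnames(vals) <- list(subjectIds, geneIds)
  out <- new("SmoothedScores",
    subjects = as.character(subjectIds), genes = as.character(geneIds),
    values = vals, iterations = it, finalDelta = delta, converged = conv,
    alpha = alpha, tol = tol
  )
  if (quantileNormalize) out <- quantileNormalizeRows(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form fixed point of the propagation update
#'
#' The iteration of [propagateBurden()] converges (for `alpha < 1`) to the
#' stationary point
#' \deqn{G^* = (1 - \alpha)\, G^0 (I - \alpha\, D N)^{-1},}
#' computed here by a direct linear solve. The system is never singular
#' for `alpha < 1` because the operator is row-stochastic (spectral radius
#' at most 1). Intended as a verification oracle and as an exact
#' alternative for small networks; cost grows cubically in the number of
#' genes.
#'
#' @inheritParams propagateBurden
#' @param alpha diffusion length in \[0, 1).
#' @return a [SmoothedScores] with `iterations = 0` and `finalDelta = 0`.
#' @export
closedFormPropagate <- function(burden, op, alpha = 0.5) {
  stopifnot(is(op, "NormalizedOperator"))
  if (is(burden, "BurdenMatrix")) {
    g0 <- as.matrix(burden@values)
    subjectIds <- burden@subjects
    geneIds <- burden@genes
  } else {
    g0 <- as.matrix(burden)
    subjectIds <- rownames(burden) %||% paste0("S", seq_len(nrow(burden)))
    geneIds <- colnames(burden) %||% op@genes
  }
  if (!identical(as.character(geneIds), op@genes)) {
    stop("burden gene order must be identical to the operator's gene order")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop("the fixed point requires alpha in [0, 1)")
  }
  m <- length(op@genes)
  a <- diag(m) - alpha * as.matrix(op@operator)
  # G* (I - alpha W) = (1 - alpha) G0  =>  t(I - alpha W) t(G*) = (1-a) t(G0)
  sol <- tryCatch(
    t(solve(t(a), (1 - alpha) * t(g0))),
    error = function(e) stop("singular propagation system: ",
      conditionMessage(e))
  )
  dimnames(sol) <- list(subjectIds, geneIds)
  new("SmoothedScores",
    subjects = as.character(subjectIds), genes = as.character(geneIds),
    values = sol, iterations = 0, finalDelta = 0, converged = TRUE,
    alpha = alpha, tol = 0
  )
}

#' Quantile-normalize subject rows of a score matrix
#'
#' Forces every subject's row to follow the same distribution: the
#' reference is the across-subject mean of order statistics (the mean of
#' all rows' sorted values), each row's values are replaced by the
#' reference value of their within-row rank, and tied values share the
#' mean of their target values. Provided for compatibility with
#' propagation pipelines that equalize per-patient score distributions;
#' off by default in [propagateBurden()] because it tends to wash out the
#' case/control difference the smoothed scores carry.
#'
#' @param scores a [SmoothedScores] or plain numeric matrix (subjects in
#'   rows).
#' @return the same type as the input, rows normalized.
#' @export
quantileNormalizeRows <- function(scores) {
  x <- if (is(scores, "SmoothedScores")) scores@values else as.matrix(scores)
  if (nrow(x) == 0 || ncol(x) == 0) return(scores)
  if (ncol(x) == 1) {
    out <- matrix(mean(x), nrow(x), 1, dimnames = dimnames(x))
    return(if (is(scores, "SmoothedScores")) {
      initialize(scores, values = out)
    } else {
      out
    })
  }
  sorted <- apply(x, 1L, sort)            # ncol(x) x nrow(x)
  ref <- rowMeans(sorted)
  out <- t(apply(x, 1L, function(v) {
    res <- numeric(length(v))
    res[order(v)] <- ref
    # tied input values share the mean of their assigned reference values
    stats::ave(res, match(v, v), FUN = mean)
  }))
  dimnames(out) <- dimnames(x)
  if (is(scores, "SmoothedScores")) {
    initialize(scores, values = out)
  } else {
    out
  }
}
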