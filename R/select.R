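#' Construct the sparsity (lambda) path for penalized selection
#'
#' Builds a log-spaced grid of `nLambda` penalty values from
#' `lambda_max` — the smallest penalty at which every coefficient of the
#' L1-penalized logistic model is zero, computed from the data — down to
#' `minRatio * lambda_max`. This is the standard path construction for
#' coordinate-descent LASSO solvers.
#'
#' @param scores subject x gene matrix or [SmoothedScores].
#' @param phenotype 0/1 vector or two-level factor (second level = case).
#' @param nLambda number of grid points (default 50).
#' @param minRatio ratio of the smallest to the largest penalty
#'   (default 0.01).
#' @param standardize standardize columns inside the fit (default TRUE).
#' @return strictly decreasing numeric vector of penalties.
#' @export
lambdaPath <- function(scores, phenotype, nLambda = 50, minRatio = 0.01,
                       standardize = TRUE) {
  x <- if (is(scores, "SmoothedScores")) scores@values else as.matrix(scores)
  y <- asPhenotype(phenotype)
  if (length(unique(y)) < 2) stop("phenotype must contain both classes")
  fit <- glmnet::glmnet(x, y,
    family = "binomial", alpha = 1, nlambda = 5,
    standardize = standardize
  )
  lmax <- fit$lambda[1]
  exp(seq(log(lmax), log(minRatio * lmax), length.out = nLambda))
}

#' L1-penalized logistic support along the lambda path
#'
#' Fits the L1-penalized logistic regression of the phenotype on the
#' smoothed gene scores (intercept unpenalized, columns standardized by
#' default) at each penalty in `lambda` and records which genes carry a
#' nonzero coefficient. Deterministic given the inputs.
#'
#' @inheritParams lambdaPath
#' @param lambda decreasing penalty sequence; computed by [lambdaPath()]
#'   when `NULL`.
#' @param maxSupport cap on the per-fit support size: path positions where
#'   more than `maxSupport` coefficients are nonzero contribute no
#'   selections (the path is truncated there). `Inf` disables the cap.
#' @return list with `lambda` and `support`, a genes x lambda logical
#'   matrix of nonzero coefficients.
#' @export
lassoSupportPath <- function(scores, phenotype, lambda = NULL,
                             nLambda = 50, minRatio = 0.01,
                             standardize = TRUE, maxSupport = Inf) {
  x <- if (is(scores, "SmoothedScores")) scores@values else as.matrix(scores)
  y <- asPhenotype(phenotype)
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (length(unique(y)) < 2) stop("phenotype must contain both classes")
  if (is.null(lambda)) {
    lambda <- lambdaPath(x, y,
      nLambda = nLambda, minRatio = minRatio,
      standardize = standardize
    )
  }
  fit <- glmnet::glmnet(x, y,
    family = "binomial", alpha = 1, lambda = lambda,
    standardize = standardize
  )
  beta <- fit$beta != 0
  # glmnet can stop early on the smallest penalties; pad with the last fit
  if (ncol(beta) < length(lambda)) {
    pad <- matrix(beta[, ncol(beta)],
      nrow = nrow(beta),
      ncol = length(lambda) - ncol(beta)
    )
    beta <- cbind(beta, pad)
  }
  support <- as.matrix(beta)
  if (is.finite(maxSupport)) {
    support[, colSums(support) > maxSupport] <- FALSE
  }
  dimnames(support) <- list(
    colnames(x) %||% paste0("G", seq_len(ncol(x))),
    NULL
  )
  list(lambda = lambda, support = support)
}

#' Stability selection for smoothed gene scores
#'
#' Identifies genes robustly associated with a binary phenotype by
#' repeated penalized fits on half-samples: each of `nResamples` resamples
#' draws half of the subjects without replacement (stratified by class so
#' that every fit sees both cases and controls), fits the L1-penalized
#' logistic path, and the selection probability of a gene at a penalty is
#' the fraction of resamples in which it received a nonzero coefficient.
#' Genes whose maximal probability along the path reaches `threshold`
#' (default 0.80) form the selected set.
#'
#' With `counting = "complementary"`, each split contributes both halves
#' (complementary pairs), giving probability granularity
#' `1/(2 nResamples)`; the default `"plain"` counts one half per resample.
#'
#' Per-fit selections are counted only over the part of the penalty path
#' where at most `maxSupport` coefficients are active. Restricting the
#' regularization region this way is what gives the 0.80 threshold its
#' error control: the expected number of falsely selected genes is
#' bounded by `maxSupport^2 / ((2 * threshold - 1) * M)`. The default
#' inverts that bound at a per-family error target of `pfer` expected
#' false selections (0.5 by default, so the expected count of spuriously
#' selected genes is below one), i.e.
#' `maxSupport = floor(sqrt((2 * threshold - 1) * M * pfer))`. The cap is
#' required in practice: an unrestricted path lets the greedy
#' small-penalty end select large supports whose strongest sample noise
#' correlations recur across half-samples, pushing pure-noise genes over
#' the threshold. Set `maxSupport = Inf` to disable.
#'
#' Resampling positions are drawn after a canonical sort of subjects by
#' identifier, so permuting the input rows does not change the result for
#' a fixed seed.
#'
#' @inheritParams lassoSupportPath
#' @param nResamples number of resamples (default 100).
#' @param threshold selection-probability cutoff (default 0.80).
#' @param seed RNG seed for reproducibility.
#' @param counting `"plain"` or `"complementary"`.
#' @param pfer per-family error target used to derive the default
#'   `maxSupport` (expected number of false selections; default 0.5).
#' @return a [StabilityResult].
#' @export
stabilitySelect <- function(scores, phenotype, lambda = NULL,
                            nResamples = 100, threshold = 0.80,
                            seed = NULL,
                            counting = c("plain", "complementary"),
                            nLambda = 50, minRatio = 0.01,
                            standardize = TRUE, maxSupport = NULL,
                            pfer = 0.5) {
  counting <- match.arg(counting)
  if (is(scores, "SmoothedScores")) {
    x <- scores@values
    rownames(x) <- scores@subjects
    colnames(x) <- scores@genes
  } else {
    x <- as.matrix(scores)
    if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("G", seq_len(ncol(x)))
  }
  y <- asPhenotype(phenotype)
  if (is.null(names(y))) {
    if (length(y) != nrow(x)) stop("phenotype length must match subjects")
    names(y) <- rownames(x)
  }
  keep <- intersect(rownames(x), names(y)[!is.na(y)])
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  s <- nrow(x)
  if (s < 20) stop("stability selection requires at least 20 subjects")
  # canonical subject order for seed-stable resampling
  ord <- order(rownames(x))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  caseIdx <- which(y == 1L)
  ctrlIdx <- which(y == 0L)
  hCase <- floor(length(caseIdx) / 2)
  hCtrl <- floor(length(ctrlIdx) / 2)
  if (hCase < 2 || hCtrl < 2) {
    stop("a class is too small for stratified split-half resampling")
  }
  if (is.null(lambda)) {
    lambda <- lambdaPath(x, y,
      nLambda = nLambda, minRatio = minRatio,
      standardize = standardize
    )
  }
  m <- ncol(x)
  l <- length(lambda)
  if (is.null(maxSupport)) {
    maxSupport <- max(3, floor(sqrt((2 * threshold - 1) * m * pfer)))
  }
  counts <- matrix(0, m, l)
  nFits <- 0L
  withSeed(seed, {
    for (b in seq_len(nResamples)) {
      half <- c(sample(caseIdx, hCase), sample(ctrlIdx, hCtrl))
      sp <- lassoSupportPath(x[half, , drop = FALSE], y[half],
        lambda = lambda, standardize = standardize,
        maxSupport = maxSupport
      )
      counts <- counts + sp$support
      nFits <- nFits + 1L
      if (counting == "complementary") {
        other <- setdiff(seq_len(s), half)
        sp2 <- lassoSupportPath(x[other, , drop = FALSE], y[other],
          lambda = lambda, standardize = standardize,
          maxSupport = maxSupport
        )
        counts <- counts + sp2$support
        nFits <- nFits + 1L
      }
    }
  })
  probs <- counts / nFits
  dimnames(probs) <- list(colnames(x), NULL)
  maxp <- apply(probs, 1L, max)
  new("StabilityResult",
    genes = colnames(x), lambda = lambda, selectionProbability = probs,
    maxProbability = maxp,
    selected = colnames(x)[maxp >= threshold],
    threshold = threshold, nResamples = nResamples, counting = counting,
    seed = if (is.null(seed)) NA_real_ else as.numeric(seed)
  )
}

#' Selection-probability trajectories for plotting
#'
#' Returns the per-gene selection-probability path over the (decreasing)
#' lambda grid. With `monotone = TRUE` (the plotting convention for
#' stability paths) each trajectory is the running maximum along the path,
#' so displayed curves are nondecreasing; the raw per-lambda probabilities
#' are kept in the [StabilityResult] itself.
#'
#' @param result a [StabilityResult].
#' @param monotone apply the running maximum along decreasing lambda.
#' @return long-format `data.frame` with columns `gene`, `lambda`,
#'   `lambdaIndex`, `probability`.
#' @export
stabilityPaths <- function(result, monotone = TRUE) {
  stopifnot(is(result, "StabilityResult"))
  p <- result@selectionProbability
  if (monotone) p <- t(apply(p, 1L, cummax))
  data.frame(
    gene = rep(result@genes, times = ncol(p)),
    lambda = rep(result@lambda, each = nrow(p)),
    lambdaIndex = rep(seq_along(result@lambda), each = nrow(p)),
    probability = as.vector(p),
    stringsAsFactors = FALSE
  )
}
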