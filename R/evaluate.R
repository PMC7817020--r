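#' Added-value comparison of nested logistic models
#'
#' Quantifies what a single smoothed gene score adds on top of established
#' covariates: a baseline logistic model (phenotype ~ covariates) is
#' compared with the extended model adding the gene score, via a
#' likelihood-ratio chi-squared test with 1 degree of freedom. McFadden's
#' pseudo-R2 (1 - logLik(model)/logLik(null intercept-only model)) is
#' reported for both. The chi-squared p-value is Bonferroni-multiplied by
#' `nGenesTested` (the number of genes for which this comparison is run,
#' typically the selected set) and capped at 1. Subjects with a missing
#' phenotype, covariate or score are dropped (complete-case), with a
#' message giving the count.
#'
#' @param phenotype 0/1 vector or two-level factor (second level = case).
#' @param covariates `data.frame` of baseline predictors (or `NULL` for an
#'   intercept-only baseline).
#' @param geneScore numeric vector, the smoothed score of one gene.
#' @param nGenesTested Bonferroni multiplier (default 1).
#' @return list with `chiSq`, `df`, `p`, `pCorrected`,
#'   `pseudoR2Baseline`, `pseudoR2Extended`, `n`, `separation` (TRUE when
#'   the extended fit shows signs of perfect separation, in which case the
#'   p-value is a machine-precision bound, flagged with a warning).
#' @export
compareModels <- function(phenotype, covariates = NULL, geneScore,
                          nGenesTested = 1) {
  y <- asPhenotype(phenotype)
  n0 <- length(y)
  df <- data.frame(.y = y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n0)
    df <- cbind(df, covariates)
  }
  df$.score <- as.numeric(geneScore)
  cc <- stats::complete.cases(df)
  if (any(!cc)) {
    message(sprintf("dropped %d incomplete subject(s)", sum(!cc)))
    df <- df[cc, , drop = FALSE]
  }
  if (length(unique(df$.y)) < 2) stop("both classes must be present")

  covTerms <- setdiff(names(df), c(".y", ".score"))
  baseForm <- stats::reformulate(
    if (length(covTerms)) covTerms else "1",
    response = ".y"
  )
  extForm <- stats::reformulate(
    c(if (length(covTerms)) covTerms, ".score"),
    response = ".y"
  )
  sep <- FALSE
  handler <- function(w) {
    msg <- conditionMessage(w)
    if (grepl("fitted probabilities numerically 0 or 1", msg) ||
        grepl("algorithm did not converge", msg)) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  }
  base <- withCallingHandlers(
    stats::glm(baseForm, data = df, family = stats::binomial()),
    warning = handler
  )
  ext <- withCallingHandlers(
    stats::glm(extForm, data = df, family = stats::binomial()),
    warning = handler
  )
  null <- stats::glm(.y ~ 1, data = df, family = stats::binomial())

  llB <- as.numeric(stats::logLik(base))
  llE <- as.numeric(stats::logLik(ext))
  ll0 <- as.numeric(stats::logLik(null))
  stat <- max(0, 2 * (llE - llB))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (sep) {
    warning("perfect separation detected; p-value is a machine-precision bound")
    p <- max(p, .Machine$double.xmin)
  }
  list(
    chiSq = stat, df = 1, p = p,
    pCorrected = min(1, p * nGenesTested),
    pseudoR2Baseline = 1 - llB / ll0,
    pseudoR2Extended = 1 - llE / ll0,
    n = nrow(df), separation = sep
  )
}

# Empirical permutation p with the +1 correction: never 0, floor
# 1/(nDraws + 1).
empiricalP <- function(nullValues, observed, greater = TRUE) {
  hits <- if (greater) sum(nullValues >= observed) else
    sum(nullValues <= observed)
  (1 + hits) / (length(nullValues) + 1)
}

#' Neighbour-overlap randomization test
#'
#' Tests whether a selected gene set falls inside the network
#' neighbourhood of a seed gene more often than chance: the observed
#' statistic is the number of selected genes within shortest-path radius
#' `radius` of the seed, and the null distribution is the same count for
#' `nDraws` uniform random gene sets of the same size drawn from the
#' tested-gene universe. The empirical p-value uses the +1 correction, so
#' its floor is `1/(nDraws + 1)` and it can never be zero.
#'
#' @param selected character vector of selected genes.
#' @param seedGene seed gene identifier (must exist in the network).
#' @param net a [GeneNetwork].
#' @param radius neighbourhood radius (default 2).
#' @param universe the gene universe random sets are drawn from (default:
#'   all network genes).
#' @param nDraws number of random sets (default 10000).
#' @param seed RNG seed.
#' @return list with `observed`, `nullValues`, `nDraws`, `empiricalP`,
#'   `neighbourhoodSize`, `universeSize`, `nSelected`.
#' @export
neighbourOverlapTest <- function(selected, seedGene, net, radius = 2,
                                 universe = genes(net), nDraws = 10000,
                                 seed = NULL) {
  stopifnot(is(net, "GeneNetwork"))
  if (!seedGene %in% net@genes) {
    stop(sprintf("seed gene '%s' not in network", seedGene))
  }
  dropped <- setdiff(selected, universe)
  if (length(dropped)) {
    message(sprintf(
      "%d selected gene(s) outside the universe were ignored",
      length(dropped)
    ))
    selected <- intersect(selected, universe)
  }
  if (!length(selected)) stop("no selected genes inside the universe")
  hood <- intersect(
    geneNeighbourhood(net, seedGene, radius = radius),
    universe
  )
  observed <- length(intersect(selected, hood))
  k <- length(selected)
  nullValues <- withSeed(seed, {
    vapply(
      seq_len(nDraws),
      function(i) length(intersect(sample(universe, k), hood)),
      numeric(1)
    )
  })
  list(
    observed = observed, nullValues = nullValues, nDraws = nDraws,
    empiricalP = empiricalP(nullValues, observed),
    neighbourhoodSize = length(hood), universeSize = length(universe),
    nSelected = k
  )
}

#' Gene-set overrepresentation (Fisher exact) with BH correction
#'
#' One-sided Fisher exact test of overrepresentation of a query gene set
#' in each annotation set, against a background universe. Annotation sets
#' are intersected with the background before testing. Reported per set:
#' `hits` (observed overlap), `expected` (|query| * |set| / |background|),
#' `OR` (conditional-MLE odds ratio from the Fisher test), `p`
#' (one-sided, alternative = greater) and `pAdjusted`
#' (Benjamini-Hochberg across sets).
#'
#' @param query character vector of genes (must be a subset of
#'   `background`).
#' @param annotationSets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param background character vector, the tested-gene universe.
#' @param fdr significance level applied to `pAdjusted` for the
#'   `significant` flag (default 0.05).
#' @return `data.frame` with one row per annotation set.
#' @export
enrichmentTest <- function(query, annotationSets, background, fdr = 0.05) {
  background <- unique(background)
  if (!length(background)) stop("empty background universe")
  bad <- setdiff(query, background)
  if (length(bad)) {
    stop(
      "query gene(s) outside the background: ",
      paste(utils::head(bad, 10), collapse = ", ")
    )
  }
  query <- unique(query)
  res <- lapply(names(annotationSets), function(nm) {
    set <- intersect(unique(annotationSets[[nm]]), background)
    a <- length(intersect(query, set))
    b <- length(query) - a
    c_ <- length(set) - a
    d <- length(background) - a - b - c_
    ft <- stats::fisher.test(
      matrix(c(a, b, c_, d), 2, 2),
      alternative = "greater"
    )
    data.frame(
      set = nm, setSize = length(set), hits = a,
      expected = length(query) * length(set) / length(background),
      OR = unname(ft$estimate), p = ft$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$pAdjusted <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$pAdjusted < fdr
  rownames(out) <- NULL
  out
}

#' Randomization control for enrichment results
#'
#' Checks that observed enrichment p-values could not be achieved by
#' chance: `nDraws` random query sets of size `querySize` are drawn from
#' the background, each is tested for overrepresentation in every
#' annotation set, and the empirical p-value per set is the fraction of
#' random sets achieving a Fisher p at most the observed one (+1
#' correction, floor `1/(nDraws + 1)`).
#'
#' @param query observed query gene set; used to compute the observed
#'   Fisher p-values (and the default `querySize`). May be `NULL` when
#'   `observedP` is supplied directly.
#' @param annotationSets named list of gene sets.
#' @param background gene universe.
#' @param querySize size of the random sets.
#' @param nDraws number of random sets (default 1000).
#' @param seed RNG seed.
#' @param observedP optional named numeric vector of observed Fisher
#'   p-values (one per annotation set), overriding computation from
#'   `query`.
#' @return named list (one entry per annotation set) of lists with
#'   `observedP`, `nullValues`, `nDraws`, `empiricalP`.
#' @export
enrichmentRandomization <- function(query = NULL, annotationSets, background,
                                    querySize = length(query),
                                    nDraws = 1000, seed = NULL,
                                    observedP = NULL) {
  background <- unique(background)
  if (querySize < 1 || querySize > length(background)) {
    stop("querySize must lie in [1, |background|]")
  }
  if (is.null(observedP)) {
    if (is.null(query)) stop("supply either query or observedP")
    obs <- enrichmentTest(query, annotationSets, background)
    observedP <- stats::setNames(obs$p, obs$set)
  }
  nullP <- withSeed(seed, {
    draws <- lapply(seq_len(nDraws), function(i) {
      rnd <- sample(background, querySize)
      enrichmentTest(rnd, annotationSets, background)$p
    })
    do.call(rbind, draws) # nDraws x nSets
  })
  colnames(nullP) <- names(annotationSets)
  out <- lapply(names(annotationSets), function(nm) {
    list(
      observedP = unname(observedP[nm]),
      nullValues = nullP[, nm],
      nDraws = nDraws,
      empiricalP = empiricalP(nullP[, nm], observedP[nm], greater = FALSE)
    )
  })
  stats::setNames(out, names(annotationSets))
}
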