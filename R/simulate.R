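#' Create a simulation specification
#'
#' Bundles the settings of a planted-signal cohort simulation: an
#' unmutated hub gene sits at the centre of a two-tier star network
#' (`n1` first-ring genes attached to the hub, `n2` second-ring genes
#' attached round-robin to the first ring), and SNV carrier status is
#' planted independently per subject and per mutated-tier gene with
#' probability `fCase` in cases and `fControl` in controls. Which tiers
#' are mutated depends on the scenario: 1 = first ring only, 2 = second
#' ring only, 3 = both. Defaults describe a desk-scale study: 200 cases,
#' 200 controls, 10 first-ring and 50 second-ring genes, 20 replicates
#' per parameter cell.
#'
#' @param nCases,nControls cohort sizes (default 200 each).
#' @param fCase,fControl carrier probabilities in mutated tiers.
#' @param scenario 1, 2 or 3.
#' @param n1,n2 ring sizes of the star fixture (defaults 10 and 50).
#' @param alpha,topPct,quantileNormalize propagation settings used by
#'   [parameterSweep()].
#' @param nReps replicates per sweep cell (default 20).
#' @param seed base RNG seed.
#' @param network optional [GeneNetwork] replacing the star fixture.
#' @param hub hub gene identifier (required with `network`; the star
#'   fixture names its hub `"HUB"`).
#' @return a [SimulationSpec].
#' @export
simulationSpec <- function(nCases = 200, nControls = 200,
                           fCase = 0.5, fControl = 0.05,
                           scenario = 3, n1 = 10, n2 = 50,
                           alpha = 0.5, topPct = 1,
                           quantileNormalize = FALSE,
                           nReps = 20, seed = 1,
                           network = NULL, hub = "HUB") {
  new("SimulationSpec",
    nCases = nCases, nControls = nControls,
    fCase = fCase, fControl = fControl, scenario = scenario,
    n1 = n1, n2 = n2, alpha = alpha, topPct = topPct,
    quantileNormalize = quantileNormalize, nReps = nReps, seed = seed,
    network = network, hub = hub
  )
}

#' Generate a fixture network
#'
#' Builds deterministic or random networks for simulations, tests and
#' demos. `"star2"` is the two-tier star used throughout the simulation
#' study: a hub (`"HUB"`), `n1` first-ring genes each connected to the
#' hub, and `n2` second-ring genes attached round-robin to the first ring
#' (each second-ring gene has degree 1). `"random_weighted"` draws each of
#' the `choose(M, 2)` gene pairs independently with probability `density`
#' and gives present edges uniform(0, 1) weights.
#'
#' @param topology `"star2"` or `"random_weighted"`.
#' @param n1,n2 ring sizes for `"star2"`.
#' @param M number of genes for `"random_weighted"` (must be >= 3).
#' @param density edge probability for `"random_weighted"`.
#' @param seed optional RNG seed (random topology only).
#' @return a [GeneNetwork] (binary for `"star2"`).
#' @export
simulateNetwork <- function(topology = c("star2", "random_weighted"),
                            n1 = 10, n2 = 50, M = 50, density = 0.1,
                            seed = NULL) {
  topology <- match.arg(topology)
  if (topology == "star2") {
    if (n1 < 1 || n2 < 0) stop("star2 needs n1 >= 1 and n2 >= 0")
    if (1 + n1 + n2 < 3) stop("network too small: need at least 3 genes")
    gn <- c(
      "HUB",
      sprintf("R1_%03d", seq_len(n1)),
      if (n2 > 0) sprintf("R2_%03d", seq_len(n2))
    )
    from <- c(rep(1L, n1), if (n2 > 0) 1L + n1 + seq_len(n2))
    to <- c(1L + seq_len(n1), if (n2 > 0) 1L + ((seq_len(n2) - 1L) %% n1) + 1L)
    m <- length(gn)
    w <- Matrix::sparseMatrix(
      i = c(from, to), j = c(to, from), x = 1, dims = c(m, m)
    )
    return(GeneNetwork(w, genes = gn, isBinary = TRUE))
  }
  if (M < 3) stop("random network needs M >= 3 genes")
  withSeed(seed, {
    gn <- sprintf("G%04d", seq_len(M))
    pairs <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
    present <- stats::runif(nrow(pairs)) < density
    if (!any(present)) {
      # guarantee a nonempty graph even at tiny densities
      present[sample.int(length(present), 1)] <- TRUE
    }
    i <- pairs[present, 1]
    j <- pairs[present, 2]
    wts <- stats::runif(sum(present))
    w <- Matrix::sparseMatrix(
      i = c(i, j), j = c(j, i), x = c(wts, wts), dims = c(M, M)
    )
    GeneNetwork(w, genes = gn, isBinary = FALSE)
  })
}

#' Simulate a case/control cohort with planted neighbourhood mutations
#'
#' Draws a burden matrix according to a [SimulationSpec]: every gene in a
#' mutated tier is set to carrier status 1 independently per subject with
#' probability `fCase` (cases) or `fControl` (controls); the hub gene and
#' all genes outside the mutated tiers stay zero. The mutated tiers are
#' the hub's first neighbours (scenario 1 or 3) and second neighbours
#' (scenario 2 or 3), computed from the network, so a supplied network is
#' handled identically to the star fixture.
#'
#' @param spec a [SimulationSpec].
#' @param seed RNG seed; defaults to the spec's seed.
#' @return list with `burden` (a status [BurdenMatrix]), `phenotype`
#'   (named 0/1 vector, cases first), `network` (the [GeneNetwork] used)
#'   and `hub`.
#' @export
simulateCohort <- function(spec, seed = spec@seed) {
  stopifnot(is(spec, "SimulationSpec"))
  net <- spec@network
  hub <- spec@hub
  if (is.null(net)) {
    net <- simulateNetwork("star2", n1 = spec@n1, n2 = spec@n2)
    hub <- "HUB"
  }
  first <- geneNeighbourhood(net, hub, radius = 1)
  second <- setdiff(geneNeighbourhood(net, hub, radius = 2), first)
  tiers <- switch(as.character(spec@scenario),
    "1" = first,
    "2" = second,
    "3" = c(first, second)
  )
  nCase <- spec@nCases
  nCtrl <- spec@nControls
  subjectIds <- c(
    sprintf("case_%04d", seq_len(nCase)),
    sprintf("ctrl_%04d", seq_len(nCtrl))
  )
  y <- stats::setNames(rep(c(1L, 0L), c(nCase, nCtrl)), subjectIds)
  m <- length(net@genes)
  tierIdx <- match(tiers, net@genes)
  vals <- withSeed(seed, {
    hits <- matrix(
      stats::rbinom(
        (nCase + nCtrl) * length(tierIdx), 1,
        rep(c(spec@fCase, spec@fControl), c(nCase, nCtrl))
      ),
      nrow = nCase + nCtrl, ncol = length(tierIdx)
    )
    v <- Matrix::Matrix(0, nCase + nCtrl, m, sparse = TRUE)
    v[, tierIdx] <- hits
    asSparse(v)
  })
  dimnames(vals) <- list(subjectIds, net@genes)
  burden <- new("BurdenMatrix",
    subjects = subjectIds, genes = net@genes,
    values = vals, encoding = "status"
  )
  list(burden = burden, phenotype = y, network = net, hub = hub)
}

#' Test the hub gene's smoothed score between cases and controls
#'
#' Two-sided rank-based two-sample test (Wilcoxon / Mann-Whitney) on the
#' hub gene's smoothed score, with an optional Bonferroni multiplier for
#' the number of parameter cells tested in a sweep. Rank tests are used
#' because smoothed-score distributions are typically far from normal; a
#' Welch t-test is available for sensitivity analysis. When all scores
#' are constant (e.g. no propagation reached the hub), the p-value is 1
#' by convention.
#'
#' @param scores a [SmoothedScores] (or subject x gene matrix).
#' @param phenotype named or aligned 0/1 vector.
#' @param hub hub gene identifier.
#' @param nTests Bonferroni multiplier (default 1).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return list with `statistic`, `p`, `pCorrected`.
#' @export
hubScoreTest <- function(scores, phenotype, hub, nTests = 1,
                         test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  x <- if (is(scores, "SmoothedScores")) as.matrix(scores) else
    as.matrix(scores)
  if (!hub %in% colnames(x)) stop("hub gene not found in the score matrix")
  y <- asPhenotype(phenotype)
  if (!is.null(names(y)) && !is.null(rownames(x))) {
    y <- y[rownames(x)]
  }
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("both classes must be present")
  }
  v <- x[, hub]
  vCase <- v[y == 1L]
  vCtrl <- v[y == 0L]
  if (stats::var(v) == 0 || (stats::var(vCase) == 0 &&
      stats::var(vCtrl) == 0 && mean(vCase) == mean(vCtrl))) {
    return(list(statistic = NA_real_, p = 1, pCorrected = 1))
  }
  ht <- if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(vCase, vCtrl, exact = FALSE))
  } else {
    stats::t.test(vCase, vCtrl)
  }
  list(
    statistic = unname(ht$statistic),
    p = ht$p.value,
    pCorrected = min(1, ht$p.value * nTests)
  )
}

#' Parameter sweep over planted frequencies and propagation settings
#'
#' Reproduces the simulation tile analysis: for every cell of the grid
#' (case frequency x control frequency x diffusion length x scenario,
#' optionally quantile normalization) and every replicate, a cohort is
#' simulated, its burden propagated over the network, and the hub score
#' tested between cases and controls. P-values are Bonferroni-corrected
#' by the number of grid cells in the sweep. Returns both the long-format
#' replicate table and the per-cell aggregation (median corrected p and a
#' significance flag at 0.05) suitable for tile plotting.
#'
#' Binarization applies when the spec's network is weighted and
#' `topPct < 100`; the star fixture is already an adjacency and is used
#' as-is.
#'
#' @param spec a [SimulationSpec] providing defaults.
#' @param fCase,fControl frequency grids (default: the spec's values).
#' @param alphas diffusion lengths to sweep.
#' @param scenarios mutation scenarios to sweep.
#' @param quantileNormalize logical values to sweep.
#' @param nReps replicates per cell.
#' @param seed base seed; replicate r of cell c uses one deterministic
#'   RNG stream.
#' @return list with `results` (long `data.frame`: scenario, alpha,
#'   top_pct, qn, f_case, f_control, rep, p, p_corrected) and `tiles`
#'   (per-cell median corrected p, `minusLog10P`, `significant`).
#' @export
parameterSweep <- function(spec = simulationSpec(),
                           fCase = spec@fCase, fControl = spec@fControl,
                           alphas = spec@alpha, scenarios = spec@scenario,
                           quantileNormalize = spec@quantileNormalize,
                           nReps = spec@nReps, seed = spec@seed) {
  grid <- expand.grid(
    f_case = fCase, f_control = fControl, alpha = alphas,
    scenario = scenarios, qn = quantileNormalize,
    KEEP.OUT.ATTRS = FALSE
  )
  nCells <- nrow(grid)
  if (!nCells) stop("empty parameter grid")

  net <- spec@network
  hub <- spec@hub
  if (is.null(net)) {
    net <- simulateNetwork("star2", n1 = spec@n1, n2 = spec@n2)
    hub <- "HUB"
  }
  if (!net@isBinary && spec@topPct < 100) {
    net <- binarizeTopEdges(net, spec@topPct)
  }
  op <- degreeNormalize(net)

  rows <- vector("list", nCells * nReps)
  k <- 0L
  for (cell in seq_len(nCells)) {
    cellSpec <- initialize(spec,
      fCase = grid$f_case[cell], fControl = grid$f_control[cell],
      scenario = grid$scenario[cell], alpha = grid$alpha[cell],
      quantileNormalize = grid$qn[cell], network = net, hub = hub
    )
    for (r in seq_len(nReps)) {
      repSeed <- (seed + 7919 * (cell - 1L) + r) %% .Machine$integer.max
      sim <- simulateCohort(cellSpec, seed = repSeed)
      sm <- propagateBurden(sim$burden, op,
        alpha = cellSpec@alpha,
        quantileNormalize = cellSpec@quantileNormalize
      )
      ht <- hubScoreTest(sm, sim$phenotype, hub, nTests = nCells)
      k <- k + 1L
      rows[[k]] <- data.frame(
        scenario = grid$scenario[cell], alpha = grid$alpha[cell],
        top_pct = spec@topPct, qn = grid$qn[cell],
        f_case = grid$f_case[cell], f_control = grid$f_control[cell],
        rep = r, p = ht$p, p_corrected = ht$pCorrected
      )
    }
  }
  results <- do.call(rbind, rows)
  tiles <- stats::aggregate(
    p_corrected ~ scenario + alpha + top_pct + qn + f_case + f_control,
    data = results, FUN = stats::median
  )
  names(tiles)[names(tiles) == "p_corrected"] <- "median_p_corrected"
  tiles$minusLog10P <- -log10(pmax(tiles$median_p_corrected,
    .Machine$double.xmin))
  tiles$significant <- tiles$median_p_corrected < 0.05
  list(results = results, tiles = tiles)
}
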