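#' Construct a GeneNetwork from a weight matrix
#'
#' Low-level constructor used by [loadNetwork()], [simulateNetwork()] and the
#' network-transforming operations. The matrix is coerced to a sparse
#' representation with explicit zeros dropped; validity (symmetry, \[0, 1\]
#' range, zero diagonal unless self-loops are allowed) is enforced.
#'
#' @param weights symmetric numeric matrix (dense or [Matrix::Matrix]) with
#'   entries in \[0, 1\].
#' @param genes gene identifiers; defaults to `rownames(weights)`.
#' @param isBinary logical; set `TRUE` for an adjacency matrix.
#' @param allowSelfLoops logical; permit nonzero diagonal entries.
#' @return a [GeneNetwork].
#' @export
GeneNetwork <- function(weights, genes = rownames(weights),
                        isBinary = FALSE, allowSelfLoops = FALSE) {
  if (is.null(genes)) {
    stop("gene identifiers are required (supply `genes` or rownames)")
  }
  w <- asSparse(weights)
  dimnames(w) <- list(genes, genes)
  new("GeneNetwork",
    genes = as.character(genes), weights = w,
    isBinary = isBinary, allowSelfLoops = allowSelfLoops
  )
}

#' Load a weighted gene-interaction network from an edge list
#'
#' Reads a whitespace/tab-separated edge list with columns geneA, geneB,
#' weight (the distribution format of tissue-specific functional networks;
#' gzipped files are read transparently) into a symmetric [GeneNetwork].
#' If the same undirected edge appears more than once with different
#' weights, the maximum is kept and a warning is emitted. Self-loop rows
#' are dropped (with a warning) unless `allowSelfLoops = TRUE`. Gene order
#' in the result is lexicographic so repeated loads are deterministic.
#'
#' @param path edge-list file; at least three columns, weights in \[0, 1\].
#' @param nameMap optional identifier translation: a two-column
#'   `data.frame` (from, to) or the path of a two-column TSV. Identifiers
#'   absent from the map are kept unchanged.
#' @param allowSelfLoops keep `gene -- gene` edges on the diagonal.
#' @return a weighted [GeneNetwork].
#' @export
loadNetwork <- function(path, nameMap = NULL, allowSelfLoops = FALSE) {
  nf <- utils::count.fields(path, comment.char = "")
  if (length(nf) == 0) stop("empty network file: ", path)
  bad <- which(nf < 3)
  if (length(bad)) {
    stop(sprintf(
      "malformed edge list: line %d has %d field(s), expected >= 3",
      bad[1], nf[bad[1]]
    ))
  }
  tab <- utils::read.table(path,
    header = FALSE, colClasses = c("character", "character", "character"),
    fill = TRUE, comment.char = ""
  )[, 1:3]
  names(tab) <- c("geneA", "geneB", "weight")
  w <- suppressWarnings(as.numeric(tab$weight))
  if (anyNA(w)) {
    stop(sprintf(
      "malformed edge list: non-numeric weight '%s' on line %d",
      tab$weight[which(is.na(w))[1]], which(is.na(w))[1]
    ))
  }
  if (any(w < 0 | w > 1)) {
    stop(sprintf(
      "edge weight outside [0, 1] on line %d: %g",
      which(w < 0 | w > 1)[1], w[which(w < 0 | w > 1)[1]]
    ))
  }
  a <- tab$geneA
  b <- tab$geneB
  if (!is.null(nameMap)) {
    if (is.character(nameMap) && length(nameMap) == 1) {
      nameMap <- utils::read.table(nameMap,
        header = FALSE,
        colClasses = "character"
      )[, 1:2]
    }
    trans <- stats::setNames(as.character(nameMap[[2]]), nameMap[[1]])
    a <- ifelse(a %in% names(trans), trans[a], a)
    b <- ifelse(b %in% names(trans), trans[b], b)
  }
  loop <- a == b
  if (any(loop) && !allowSelfLoops) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loop)))
    a <- a[!loop]
    b <- b[!loop]
    w <- w[!loop]
  }
  if (!length(w)) stop("network has no usable edges")
  # canonical undirected key, then resolve duplicates by maximum weight
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(w, key, max)
    spread <- tapply(w, key, function(v) max(v) - min(v))
    if (any(spread > 0)) {
      warning(sprintf(
        "%d duplicated edge(s) with differing weights; kept the maximum",
        sum(spread > 0)
      ))
    }
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    lo <- vapply(parts, `[`, "", 1)
    hi <- vapply(parts, `[`, "", 2)
    w <- as.numeric(agg)
  }
  gn <- sort(unique(c(lo, hi)))
  i <- match(lo, gn)
  j <- match(hi, gn)
  wm <- Matrix::sparseMatrix(
    i = c(i, j[i != j]), j = c(j, i[i != j]),
    x = c(w, w[i != j]), dims = c(length(gn), length(gn))
  )
  GeneNetwork(wm, genes = gn, isBinary = all(w %in% c(0, 1)),
    allowSelfLoops = allowSelfLoops)
}

# Upper-triangle (i <= j) nonzero edges as a data.frame(i, j, w),
# self-loops included only when present on the diagonal.
edgeTable <- function(net) {
  tm <- as(Matrix::triu(net@weights), "TsparseMatrix")
  keep <- tm@x != 0
  data.frame(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L, w = tm@x[keep])
}

#' Binarize a weighted network by retaining the top P% of edges
#'
#' Converts a weighted network to an unweighted adjacency by keeping
#' exactly `k = ceiling(topPct/100 * E)` edges of highest weight, where E
#' is the number of nonzero undirected edges. Ties at the cut weight are
#' broken by lexicographic (geneA, geneB) order, so the result is
#' deterministic. The percentage refers to existing nonzero edges, not to
#' all gene pairs.
#'
#' @param net a weighted [GeneNetwork] (not already binary).
#' @param topPct percentage of edges to keep, in (0, 100\]; default 1.
#' @return a binary [GeneNetwork] on the same gene set.
#' @export
binarizeTopEdges <- function(net, topPct = 1) {
  stopifnot(is(net, "GeneNetwork"))
  if (net@isBinary) stop("network is already binary")
  if (!is.numeric(topPct) || topPct <= 0 || topPct > 100) {
    stop("topPct must lie in (0, 100]")
  }
  ed <- edgeTable(net)
  e <- nrow(ed)
  if (e == 0) stop("network has no edges")
  k <- ceiling(topPct / 100 * e)
  ord <- order(-ed$w, net@genes[ed$i], net@genes[ed$j])
  keep <- ed[ord[seq_len(k)], , drop = FALSE]
  offdiag <- keep$i != keep$j
  m <- length(net@genes)
  wm <- Matrix::sparseMatrix(
    i = c(keep$i, keep$j[offdiag]), j = c(keep$j, keep$i[offdiag]),
    x = 1, dims = c(m, m)
  )
  GeneNetwork(wm, genes = net@genes, isBinary = TRUE,
    allowSelfLoops = net@allowSelfLoops)
}

#' Row-normalize a network into the diffusion operator
#'
#' Divides each row of the weight matrix N by the node strength
#' (row sum), yielding the row-stochastic product D N used by
#' [propagateBurden()], where D is the diagonal matrix of inverse node
#' strengths. Rows of isolated genes (strength 0) are left all-zero:
#' propagation never moves mass into or out of them through the network
#' term, but their indices stay aligned with the burden matrix.
#'
#' @param net a [GeneNetwork] (weighted or binary; after binarization the
#'   node strength equals the degree).
#' @return a [NormalizedOperator].
#' @export
degreeNormalize <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  s <- Matrix::rowSums(net@weights)
  inv <- ifelse(s > 0, 1 / s, 0)
  op <- Matrix::Diagonal(x = inv) %*% net@weights
  op <- asSparse(op)
  dimnames(op) <- list(net@genes, net@genes)
  new("NormalizedOperator", genes = net@genes, operator = op)
}

#' Degree-preserving network randomization by double edge swaps
#'
#' Shuffles a binary network while preserving every node's degree exactly:
#' repeatedly picks two edges (a,b) and (c,d) at random and rewires them to
#' (a,d) and (c,b), rejecting any swap that would create a self-loop or a
#' duplicate edge. This is the standard null model used to test whether an
#' association signal depends on the real network's wiring rather than its
#' degree sequence alone.
#'
#' @param net a binary [GeneNetwork] with at least 2 edges.
#' @param nSwaps number of attempted swaps; defaults to `10 * E`, a common
#'   mixing heuristic.
#' @param seed optional RNG seed for reproducibility.
#' @return a binary [GeneNetwork] with the same degree sequence.
#' @export
randomizePreservingDegree <- function(net, nSwaps = NULL, seed = NULL) {
  stopifnot(is(net, "GeneNetwork"))
  if (!net@isBinary) stop("randomization requires a binarized network")
  ed <- edgeTable(net)
  ed <- ed[ed$i != ed$j, , drop = FALSE]
  e <- nrow(ed)
  if (e < 2) stop("need at least 2 edges to swap")
  if (is.null(nSwaps)) nSwaps <- 10L * e
  if (nSwaps < 1) stop("nSwaps must be >= 1")
  edges <- cbind(ed$i, ed$j)
  present <- new.env(hash = TRUE, parent = emptyenv(), size = 2L * e)
  ekey <- function(u, v) paste0(min(u, v), ":", max(u, v))
  for (r in seq_len(e)) assign(ekey(edges[r, 1], edges[r, 2]), TRUE, present)
  withSeed(seed, {
    for (it in seq_len(nSwaps)) {
      idx <- sample.int(e, 2)
      a <- edges[idx[1], 1]; b <- edges[idx[1], 2]
      c_ <- edges[idx[2], 1]; d <- edges[idx[2], 2]
      # randomize which endpoint pairing is proposed
      if (stats::runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (a == d || c_ == b) next
      k1 <- ekey(a, d); k2 <- ekey(c_, b)
      if (exists(k1, present, inherits = FALSE) ||
          exists(k2, present, inherits = FALSE) || k1 == k2) {
        next
      }
      rm(list = c(ekey(a, b), ekey(c_, d)), envir = present)
      assign(k1, TRUE, present)
      assign(k2, TRUE, present)
      edges[idx[1], ] <- c(a, d)
      edges[idx[2], ] <- c(c_, b)
    }
  })
  m <- length(net@genes)
  wm <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = 1, dims = c(m, m)
  )
  GeneNetwork(wm, genes = net@genes, isBinary = TRUE,
    allowSelfLoops = net@allowSelfLoops)
}

#' Genes within a shortest-path radius of a seed gene
#'
#' Returns the ego neighbourhood of a gene: all genes at shortest-path
#' distance at most `radius` from the seed (any nonzero edge counts as one
#' step). Used to define candidate communities around hub genes and as the
#' target set of the neighbour-overlap randomization test.
#'
#' @param net a [GeneNetwork].
#' @param gene seed gene identifier (must exist in the network).
#' @param radius maximum shortest-path distance (positive integer;
#'   typically 1 or 2).
#' @param includeSeed include the seed gene itself in the result.
#' @return character vector of gene identifiers (sorted).
#' @export
geneNeighbourhood <- function(net, gene, radius = 1, includeSeed = FALSE) {
  stopifnot(is(net, "GeneNetwork"))
  if (!gene %in% net@genes) {
    near <- utils::head(agrep(gene, net@genes, value = TRUE,
      ignore.case = TRUE), 5)
    stop(sprintf(
      "gene '%s' not in network%s", gene,
      if (length(near)) paste0("; nearest matches: ",
        paste(near, collapse = ", ")) else ""
    ))
  }
  if (radius < 1 || radius != round(radius)) {
    stop("radius must be a positive integer")
  }
  adj <- net@weights != 0
  frontier <- match(gene, net@genes)
  reached <- logical(length(net@genes))
  reached[frontier] <- TRUE
  for (r in seq_len(radius)) {
    nxt <- which(Matrix::colSums(adj[frontier, , drop = FALSE]) > 0)
    frontier <- nxt[!reached[nxt]]
    if (!length(frontier)) break
    reached[frontier] <- TRUE
  }
  out <- net@genes[reached]
  if (!includeSeed) out <- setdiff(out, gene)
  sort(out)
}
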