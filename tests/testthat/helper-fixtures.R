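# Fixture builders shared across test files. Oracles used to verify
# package output are kept independent of the code paths they check.

# Write an edge list to a temp file and return its path.
writeEdgeList <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Dense symmetric weight matrix -> GeneNetwork, for hand-built toys.
toyNetwork <- function(w, genes = LETTERS[seq_len(nrow(w))],
                       isBinary = all(w %in% c(0, 1))) {
  GeneNetwork(w, genes = genes, isBinary = isBinary)
}

# Path graph A-B-C-... with unit weights.
pathNetwork <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  toyNetwork(w)
}

# Star: hub (first gene) connected to n leaves, unit weights.
starNetwork <- function(nLeaves) {
  w <- matrix(0, nLeaves + 1, nLeaves + 1)
  w[1, -1] <- w[-1, 1] <- 1
  toyNetwork(w, genes = c("HUB", paste0("L", seq_len(nLeaves))))
}

# Random symmetric weighted graph built directly (independent of
# simulateNetwork) for property tests.
randomWeightedNetwork <- function(m, density = 0.3) {
  w <- matrix(0, m, m)
  up <- which(upper.tri(w))
  on <- up[runif(length(up)) < density]
  if (!length(on)) on <- sample(up, 1)
  w[on] <- runif(length(on))
  w <- w + t(w)
  toyNetwork(w, genes = sprintf("g%03d", seq_len(m)))
}

# Degree sequence oracle straight from the weight matrix.
degreeSequence <- function(net) {
  sort(as.integer(Matrix::rowSums(edgeWeights(net) != 0)))
}

# BurdenMatrix from a plain 0/1 matrix.
toyBurden <- function(m, subjects = rownames(m), genes = colnames(m),
                      encoding = "status") {
  if (is.null(subjects)) subjects <- paste0("s", seq_len(nrow(m)))
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(m)))
  v <- methods::as(methods::as(
    Matrix::Matrix(m, sparse = TRUE), "generalMatrix"
  ), "CsparseMatrix")
  dimnames(v) <- list(subjects, genes)
  methods::new("BurdenMatrix",
    subjects = subjects, genes = genes,
    values = Matrix::drop0(v), encoding = encoding
  )
}

# Exact one-sided hypergeometric tail by explicit enumeration:
# P(X >= hits) for |query| draws from a universe of size n containing
# setSize successes.
hypergeomTailEnum <- function(hits, querySize, setSize, n) {
  ks <- hits:min(querySize, setSize)
  sum(choose(setSize, ks) * choose(n - setSize, querySize - ks)) /
    choose(n, querySize)
}
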