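test_that("edge lists load into symmetric networks with lexicographic gene order", {
  f <- writeEdgeList(c("A B 0.9", "B C 0.4"))
  net <- loadNetwork(f)
  expect_s4_class(net, "GeneNetwork")
  expect_identical(genes(net), c("A", "B", "C"))
  w <- edgeWeights(net)
  expect_equal(w["A", "B"], 0.9)
  expect_equal(w["B", "C"], 0.4)
  expect_equal(w["A", "C"], 0)
  expect_true(Matrix::isSymmetric(w, tol = 0))

  # gene order deterministic regardless of file order
  f2 <- writeEdgeList(c("B C 0.4", "A B 0.9"))
  expect_identical(genes(loadNetwork(f2)), c("A", "B", "C"))
})

test_that("duplicated edges keep the maximum weight with a warning", {
  f <- writeEdgeList(c("A B 0.9", "B A 0.7"))
  expect_warning(net <- loadNetwork(f), "maximum")
  expect_equal(edgeWeights(net)["A", "B"], 0.9)
  expect_equal(numEdges(net), 1L)
})

test_that("self-loops are dropped by default and kept on request", {
  f <- writeEdgeList(c("A A 0.5", "A B 0.3"))
  expect_warning(net <- loadNetwork(f), "self-loop")
  expect_equal(Matrix::diag(edgeWeights(net))[["A"]], 0)
  netLoop <- loadNetwork(f, allowSelfLoops = TRUE)
  expect_equal(edgeWeights(netLoop)["A", "A"], 0.5)
})

test_that("malformed lines and out-of-range weights are rejected with context", {
  expect_error(loadNetwork(writeEdgeList(c("A B 0.9", "B C"))), "line 2")
  expect_error(loadNetwork(writeEdgeList("A B 1.5")), "\\[0, 1\\]")
  expect_error(loadNetwork(writeEdgeList("A B x")), "line 1")
  empty <- tempfile()
  file.create(empty)
  expect_error(loadNetwork(empty), "empty")
})

test_that("identifier translation applies to both gene columns", {
  f <- writeEdgeList(c("1 2 0.9", "2 3 0.4"))
  map <- data.frame(from = c("1", "2", "3"), to = c("TP53", "EGFR", "MYC"))
  net <- loadNetwork(f, nameMap = map)
  expect_identical(genes(net), sort(c("TP53", "EGFR", "MYC")))
  expect_equal(edgeWeights(net)["TP53", "EGFR"], 0.9)
})

test_that("binarization keeps exactly ceiling(P% of E) top edges", {
  # 10 edges with distinct weights, P = 20 -> the 2 heaviest survive
  set.seed(41)
  m <- 8
  w <- matrix(0, m, m)
  pairs <- which(upper.tri(w))[1:10]
  wts <- sample(seq(0.05, 0.95, length.out = 10))
  w[pairs] <- wts
  w <- w + t(w)
  net <- toyNetwork(w, genes = sprintf("g%d", 1:m))
  bin <- binarizeTopEdges(net, 20)
  expect_true(isBinary(bin))
  expect_equal(numEdges(bin), 2L)
  keptW <- w[as.matrix(edgeWeights(bin)) == 1]
  expect_setequal(unique(keptW), sort(wts, decreasing = TRUE)[1:2])

  # P = 100 keeps all edges as weight 1
  full <- binarizeTopEdges(net, 100)
  expect_equal(numEdges(full), 10L)
  expect_true(all(edgeWeights(full)@x == 1))
})

test_that("binarization ties at the cut break lexicographically", {
  # 4 edges all weight 0.5: D-A, C-B, A-B, C-D; P=25 keeps 1 edge, the
  # lexicographically first (geneA, geneB) pair, i.e. A-B
  w <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  w["D", "A"] <- w["A", "D"] <- 0.5
  w["C", "B"] <- w["B", "C"] <- 0.5
  w["A", "B"] <- w["B", "A"] <- 0.5
  w["C", "D"] <- w["D", "C"] <- 0.5
  bin <- binarizeTopEdges(toyNetwork(w), 25)
  expect_equal(numEdges(bin), 1L)
  expect_equal(edgeWeights(bin)["A", "B"], 1)
})

test_that("binarization count matches a full-sort oracle on random graphs", {
  set.seed(7)
  for (i in 1:20) {
    net <- randomWeightedNetwork(sample(6:15, 1))
    e <- numEdges(net)
    p <- runif(1, 1, 100)
    k <- ceiling(p / 100 * e) # oracle: sort all edges, take top k
    bin <- binarizeTopEdges(net, p)
    expect_equal(numEdges(bin), k)
    # every kept edge weight >= every dropped edge weight
    wOrig <- as.matrix(edgeWeights(net))
    kept <- as.matrix(edgeWeights(bin)) == 1
    up <- upper.tri(wOrig) & wOrig > 0
    if (any(up & !kept) && any(up & kept)) {
      expect_gte(min(wOrig[up & kept]), max(wOrig[up & !kept]))
    }
  }
})

test_that("degree normalization yields row-stochastic rows and keeps zero rows", {
  # weights row already summing to 1 is unchanged
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.9
  w[1, 3] <- w[3, 1] <- 0.1
  op <- degreeNormalize(toyNetwork(w))
  expect_equal(as.numeric(operatorMatrix(op)[1, ]), c(0, 0.9, 0.1))

  # binary star: hub row 0.25 each, leaf rows a single 1
  opStar <- degreeNormalize(starNetwork(4))
  om <- as.matrix(operatorMatrix(opStar))
  expect_equal(unname(om[1, -1]), rep(0.25, 4))
  expect_equal(unname(om[-1, 1]), rep(1, 4))

  # isolated gene keeps an all-zero row
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 0.5
  op2 <- degreeNormalize(toyNetwork(w2))
  expect_equal(sum(operatorMatrix(op2)[3, ]), 0)
  rs <- Matrix::rowSums(operatorMatrix(op2))
  expect_true(all(abs(rs - 1) <= 1e-12 | rs == 0))
})

test_that("degree-preserving randomization keeps the exact degree sequence", {
  set.seed(13)
  for (i in 1:15) {
    net <- binarizeTopEdges(randomWeightedNetwork(sample(6:14, 1)), 100)
    rnd <- randomizePreservingDegree(net, seed = i)
    expect_identical(degreeSequence(rnd), degreeSequence(net))
    expect_true(all(Matrix::diag(edgeWeights(rnd)) == 0))
    expect_true(Matrix::isSymmetric(edgeWeights(rnd), tol = 0))
  }
})

test_that("randomizing a 4-cycle yields a 2-regular graph, reproducibly", {
  w <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  for (p in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    w[p[1], p[2]] <- w[p[2], p[1]] <- 1
  }
  net <- toyNetwork(w)
  r1 <- randomizePreservingDegree(net, nSwaps = 200, seed = 5)
  expect_equal(degreeSequence(r1), rep(2L, 4))
  r2 <- randomizePreservingDegree(net, nSwaps = 200, seed = 5)
  expect_identical(as.matrix(edgeWeights(r1)), as.matrix(edgeWeights(r2)))
  expect_error(
    randomizePreservingDegree(toyNetwork(matrix(0, 2, 2) + diag(0, 2))),
    "2 edges"
  )
})

test_that("neighbourhoods follow shortest-path distance", {
  path3 <- pathNetwork(3) # A-B-C
  expect_identical(geneNeighbourhood(path3, "A", 1), "B")
  expect_identical(geneNeighbourhood(path3, "A", 2), c("B", "C"))
  expect_identical(
    geneNeighbourhood(path3, "A", 2, includeSeed = TRUE),
    c("A", "B", "C")
  )
  # star, seed at a leaf: radius 2 reaches the hub and all other leaves
  star <- starNetwork(4)
  expect_setequal(
    geneNeighbourhood(star, "L1", 2),
    c("HUB", "L2", "L3", "L4")
  )
  expect_error(geneNeighbourhood(path3, "Z9"), "not in network")
})

test_that("neighbourhoods agree with an igraph ego oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (i in 1:10) {
    net <- randomWeightedNetwork(12, density = 0.25)
    g <- igraph::graph_from_adjacency_matrix(
      as.matrix(edgeWeights(net)) != 0,
      mode = "undirected"
    )
    seedGene <- sample(genes(net), 1)
    for (r in 1:2) {
      ours <- geneNeighbourhood(net, seedGene, radius = r)
      ref <- setdiff(
        names(unlist(igraph::ego(g, order = r, nodes = seedGene)[[1]])),
        seedGene
      )
      expect_setequal(ours, ref)
    }
  }
})

test_that("network round-trips through the edge-list writer", {
  net <- randomWeightedNetwork(8)
  f <- tempfile(fileext = ".tsv")
  writeNetwork(net, f)
  back <- loadNetwork(f)
  expect_identical(genes(back), genes(net))
  expect_equal(
    as.matrix(edgeWeights(back)), as.matrix(edgeWeights(net)),
    tolerance = 1e-12
  )
})
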