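variantRecord <- function(id, gene, consequence, maf, cadd) {
  data.frame(
    variant_id = id, gene = gene, consequence = consequence,
    maf = maf, cadd_phred = cadd, stringsAsFactors = FALSE
  )
}

test_that("variant filtering applies MAF, consequence and strict CADD rules", {
  # fails MAF (0.02 >= 0.01)
  expect_equal(nrow(filterVariants(
    variantRecord("v1", "G1", "missense", 0.02, 35)
  )), 0)
  # CADD cutoff is strict: exactly 20 is excluded
  expect_equal(nrow(filterVariants(
    variantRecord("v2", "G1", "missense", 0.001, 20.0)
  )), 0)
  expect_equal(nrow(filterVariants(
    variantRecord("v3", "G1", "missense", 0.001, 20.01)
  )), 1)
  # MAF cutoff is strict too
  expect_equal(nrow(filterVariants(
    variantRecord("v4", "G1", "missense", 0.01, 30)
  )), 0)
})

test_that("six records spanning all filter branches keep the 2 expected survivors", {
  recs <- rbind(
    variantRecord("keep1", "G1", "missense", 0.001, 30),   # passes all
    variantRecord("common", "G1", "missense", 0.05, 30),   # fails MAF
    variantRecord("benign", "G2", "missense", 0.001, 10),  # fails CADD
    variantRecord("synon", "G2", "synonymous", 0.001, 30), # wrong class
    variantRecord("fsNoCadd", "G3", "frameshift", 0.001, NA), # CADD missing
    variantRecord("keep2", "G3", "stop-gain", 0.001, 40)   # passes all
  )
  expect_warning(
    kept <- filterVariants(recs),
    "missing required annotations"
  )
  expect_identical(kept$variant_id, c("keep1", "keep2"))

  # the frameshift exemption rescues the CADD-less frameshift
  keptEx <- suppressWarnings(
    filterVariants(recs, frameshiftCaddExempt = TRUE)
  )
  expect_identical(keptEx$variant_id, c("keep1", "fsNoCadd", "keep2"))

  # alternative high-impact set: stop-gain/stop-loss/frameshift only
  keptAlt <- filterVariants(recs,
    consequences = c("stop-gain", "stop-loss", "frameshift"),
    frameshiftCaddExempt = TRUE
  )
  expect_identical(keptAlt$variant_id, c("fsNoCadd", "keep2"))
})

# 4 subjects x 5 variants toy panel used by several blocks:
# genes: v1,v2 -> GA; v3 -> GB; v4,v5 -> GC
toyPanel <- function() {
  variants <- rbind(
    variantRecord("v1", "GA", "missense", 0.001, 30),
    variantRecord("v2", "GA", "missense", 0.002, 25),
    variantRecord("v3", "GB", "stop-gain", 0.001, 40),
    variantRecord("v4", "GC", "missense", 0.003, 22),
    variantRecord("v5", "GC", "missense", 0.004, 28)
  )
  g <- matrix(
    c(
      1, 1, 0, 1, 1, # s1: GA x2, GC x2
      0, 0, 1, 0, 0, # s2: GB only
      0, 0, 0, 0, 0, # s3: nothing
      1, 0, 1, 0, 1  # s4: GA, GB, GC
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("s", 1:4), paste0("v", 1:5))
  )
  list(variants = variants, genotypes = g)
}

test_that("burden construction matches the hand tally in both encodings", {
  tp <- toyPanel()
  status <- buildBurden(tp$variants, tp$genotypes, encoding = "status")
  counts <- buildBurden(tp$variants, tp$genotypes, encoding = "burden")
  expectStatus <- matrix(
    c(
      1, 0, 1,
      0, 1, 0,
      0, 0, 0,
      1, 1, 1
    ),
    4, 3, byrow = TRUE,
    dimnames = list(paste0("s", 1:4), c("GA", "GB", "GC"))
  )
  expectCounts <- matrix(
    c(
      2, 0, 2,
      0, 1, 0,
      0, 0, 0,
      1, 1, 1
    ),
    4, 3, byrow = TRUE,
    dimnames = list(paste0("s", 1:4), c("GA", "GB", "GC"))
  )
  expect_equal(as.matrix(status), expectStatus)
  expect_equal(as.matrix(counts), expectCounts)
  expect_identical(burdenEncoding(status), "status")
  expect_identical(burdenEncoding(counts), "burden")
})

test_that("status equals the indicator of the count encoding; column sums match a per-subject scan", {
  set.seed(91)
  nSub <- 30
  nVar <- 40
  geneOf <- sample(paste0("G", 1:8), nVar, replace = TRUE)
  variants <- data.frame(
    variant_id = paste0("v", 1:nVar), gene = geneOf,
    consequence = "missense", maf = 0.001, cadd_phred = 30
  )
  g <- matrix(rbinom(nSub * nVar, 1, 0.1),
    nSub, nVar,
    dimnames = list(paste0("s", 1:nSub), paste0("v", 1:nVar))
  )
  status <- buildBurden(variants, g, encoding = "status")
  counts <- buildBurden(variants, g, encoding = "burden")
  expect_equal(
    as.matrix(status),
    (as.matrix(counts) > 0) + 0
  )
  # independent oracle: per-subject scan over the raw genotype rows
  carriers <- sapply(genes(status), function(gene) {
    vs <- variants$variant_id[variants$gene == gene]
    sum(apply(g[, vs, drop = FALSE], 1, function(r) any(r > 0)))
  })
  expect_equal(unname(colSums(as.matrix(status))), unname(carriers))
})

test_that("burden columns align to a companion network's gene order", {
  tp <- toyPanel()
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  net <- toyNetwork(w, genes = c("GC", "GA", "GX", "GB")) # non-alphabetical
  b <- buildBurden(tp$variants, tp$genotypes, network = net)
  expect_identical(genes(b), c("GC", "GA", "GX", "GB"))
  expect_equal(sum(as.matrix(b)[, "GX"]), 0) # no variants -> zero column

  # a variant in a gene outside the network is dropped with a message
  extra <- rbind(tp$variants, variantRecord("v6", "GZ", "missense", 0.001, 30))
  gt <- cbind(tp$genotypes, v6 = c(1, 0, 0, 0))
  expect_message(
    b2 <- buildBurden(extra, gt, network = net),
    "absent from the network"
  )
  expect_identical(genes(b2), genes(net))
  expect_equal(as.matrix(b2), as.matrix(b))
})

test_that("unknown variant ids are reported with offenders listed", {
  tp <- toyPanel()
  bad <- tp$variants
  bad$variant_id[1] <- "missingVariant"
  expect_error(
    buildBurden(bad, tp$genotypes),
    "missingVariant"
  )
})

test_that("odds-ratio orientation calls risk and protective directions", {
  # carriers: 8 cases, 2 controls; non-carriers 42 / 48 -> OR ~ 4.57 risk
  nCase <- 50
  nCtrl <- 50
  carrier <- c(rep(1, 8), rep(0, 42), rep(1, 2), rep(0, 48))
  m <- cbind(gRisk = carrier, gProt = rev(carrier))
  rownames(m) <- c(paste0("case", 1:nCase), paste0("ctrl", 1:nCtrl))
  y <- setNames(rep(c(1, 0), c(nCase, nCtrl)), rownames(m))
  b <- toyBurden(m)
  ob <- orientEffects(b, y, mode = "signed")
  ot <- orientation(ob)
  expect_equal(
    ot$oddsRatio[ot$gene == "gRisk"], (8 * 48) / (2 * 42),
    tolerance = 1e-12
  )
  expect_identical(ot$direction, c("risk", "protective"))
  # risk column unchanged, protective column negated
  expect_equal(as.matrix(ob)[, "gRisk"], m[, "gRisk"])
  expect_equal(as.matrix(ob)[, "gProt"], -m[, "gProt"])
  expect_identical(burdenEncoding(ob), "signed_status")

  # mode none: values untouched, metadata still attached
  obNone <- orientEffects(b, y, mode = "none")
  expect_equal(as.matrix(obNone), m)
  expect_equal(nrow(orientation(obNone)), 2)

  # zeroing modes
  expect_equal(sum(as.matrix(orientEffects(b, y, "zero_protective"))[, "gProt"]), 0)
  expect_equal(sum(as.matrix(orientEffects(b, y, "zero_risk"))[, "gRisk"]), 0)
})

test_that("signed orientation is idempotent and preserves magnitudes", {
  set.seed(5)
  m <- matrix(rbinom(200, 1, 0.2), 20, 10,
    dimnames = list(paste0("s", 1:20), paste0("g", 1:10))
  )
  y <- setNames(rep(c(1, 0), each = 10), rownames(m))
  once <- orientEffects(toyBurden(m), y, mode = "signed")
  twice <- orientEffects(once, y, mode = "signed")
  expect_identical(orientation(once), orientation(twice))
  expect_equal(as.matrix(twice), as.matrix(once))
  expect_equal(abs(as.matrix(once)), m)
})

test_that("all-carrier and no-carrier genes stay undetermined and unchanged", {
  m <- cbind(
    gAll = rep(1, 20), gNone = rep(0, 20),
    gMix = rep(c(1, 0), 10)
  )
  rownames(m) <- paste0("s", 1:20)
  y <- setNames(rep(c(1, 0), each = 10), rownames(m))
  ob <- orientEffects(toyBurden(m), y, mode = "signed")
  ot <- orientation(ob)
  expect_identical(ot$direction[ot$gene == "gAll"], "undetermined")
  expect_identical(ot$direction[ot$gene == "gNone"], "undetermined")
  expect_equal(as.matrix(ob)[, "gAll"], m[, "gAll"])
  # contingency counts always sum to the phenotyped sample size
  expect_true(all(rowSums(ot[, c(
    "carrierCase", "carrierControl",
    "nonCarrierCase", "nonCarrierControl"
  )]) == 20))
})
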