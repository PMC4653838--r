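# First-stage correlation features, stacking, and the integrated similarity.

test_that("row-wise correlation matches its definition on canonical pairs", {
  x <- OmicsMatrix(rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 1, 2)))
  p <- featureValues(correlationSimilarity(x, "pearson"))
  expect_equal(p["a", "b"], 1)                       # perfect linear relation
  expect_equal(diag(p), c(a = 1, b = 1, c = 1))

  y <- OmicsMatrix(rbind(a = c(1, 2, 3), b = c(10, 100, 1000), c = c(5, 1, 2)))
  s <- featureValues(correlationSimilarity(y, "spearman"))
  p2 <- featureValues(correlationSimilarity(y, "pearson"))
  expect_equal(s["a", "b"], 1)                       # monotone map preserves ranks
  expect_lt(p2["a", "b"], 1)

  # tied values use midranks; checked against a counting-based oracle
  z <- OmicsMatrix(rbind(a = c(1, 2, 2, 3), b = c(1, 3, 2, 4), c = c(4, 1, 3, 2)))
  sz <- featureValues(correlationSimilarity(z, "spearman"))
  expect_equal(sz["a", "b"], loopSpearman(c(1, 2, 2, 3), c(1, 3, 2, 4)),
               tolerance = 1e-12)
})

test_that("zero-variance rows get similarity 0 and keep a unit diagonal", {
  x <- OmicsMatrix(rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(3, 1, 2)))
  expect_warning(sim <- correlationSimilarity(x, "pearson"), "zero variance")
  v <- featureValues(sim)
  expect_equal(v["b", "a"], 0)
  expect_equal(v["b", "c"], 0)
  expect_equal(v["b", "b"], 1)
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(OmicsMatrix(matrix(1:3, 3, 1,
    dimnames = list(c("a", "b", "c"), NULL))), "2 feature columns")
  expect_error(OmicsMatrix(rbind(a = c(1, NA, 3), b = 1:3, c = 3:1)),
               "non-finite")
  expect_error(OmicsMatrix(rbind(a = 1:3, a = 4:6, b = 7:9)), "duplicated")
  m <- matrix(rnorm(6), 3, 2); rownames(m) <- c("a", "b", "c")
  expect_error(correlationSimilarity(OmicsMatrix(m), "kendall"))
})

test_that("stacking concatenates similarity blocks in order without rescaling", {
  ds <- lapply(1:3, function(k) randomOmics(10, 8, seed = k))
  sims <- unlist(lapply(ds, function(d) list(
    correlationSimilarity(d, "pearson"),
    correlationSimilarity(d, "spearman"))), recursive = FALSE)
  y <- stackFeatures(sims)
  expect_equal(dim(featureValues(y)), c(10, 2 * 10 * 3))    # M x 2MK
  expect_true(all(abs(featureValues(y)) <= 1))

  # single Pearson matrix stacks to itself
  y1 <- stackFeatures(list(sims[[1]]))
  expect_equal(unname(featureValues(y1)), unname(featureValues(sims[[1]])))

  # manual block placement: with order [P1 S1 P2 S2], columns 5..8 are S1
  d2 <- lapply(4:5, function(k) randomOmics(4, 6, seed = k))
  p1 <- correlationSimilarity(d2[[1]], "pearson")
  s1 <- correlationSimilarity(d2[[1]], "spearman")
  p2 <- correlationSimilarity(d2[[2]], "pearson")
  s2 <- correlationSimilarity(d2[[2]], "spearman")
  y2 <- stackFeatures(list(p1, s1, p2, s2))
  expect_equal(unname(featureValues(y2)[, 5:8]), unname(featureValues(s1)))
  expect_equal(blockIndex(y2)$kind,
               rep(c("pearson", "spearman"), each = 4, times = 2))
})

test_that("stacking rejects misaligned patients", {
  a <- correlationSimilarity(randomOmics(5, 6, seed = 1))
  bmat <- featureValues(randomOmics(5, 6, seed = 2))
  rownames(bmat) <- rev(rownames(bmat))
  b <- correlationSimilarity(OmicsMatrix(bmat))
  expect_error(stackFeatures(list(a, b)), "align")
})

test_that("second-stage integration is Pearson correlation of stacked rows", {
  # identical rows correlate at 1, sign-flipped centered rows at -1
  y <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1)) / 4
  z <- featureValues(integrateFeatures(y))
  expect_equal(z["a", "b"], 1)
  expect_equal(z["a", "c"], -1)

  # 4 x 6 toy against the brute-force pairwise oracle
  set.seed(7)
  y2 <- matrix(runif(24, -1, 1), 4, 6,
               dimnames = list(paste0("p", 1:4), NULL))
  z2 <- featureValues(integrateFeatures(y2))
  for (a in 1:4) for (b in 1:4)
    expect_equal(z2[a, b], if (a == b) 1 else loopPearson(y2[a, ], y2[b, ]),
                 tolerance = 1e-12)

  # constant rows are flagged and zeroed
  y3 <- rbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(3, 1, 2)) / 3
  expect_warning(z3 <- integrateFeatures(y3), "zero variance")
  expect_equal(featureValues(z3)["b", "a"], 0)
})

test_that("the pipeline composes stage I-III and matches the loop oracle", {
  # K = 1, Pearson-only: Z is the correlation of the rows of P
  d <- randomOmics(6, 9, seed = 11)
  p <- correlationSimilarity(d, "pearson")
  zExpected <- integrateFeatures(stackFeatures(list(p)))
  z <- ibfe(list(d), variant = "ibfe2")
  expect_equal(featureValues(z), featureValues(zExpected))
  expect_equal(simMethod(z), "integrated")

  # tiny random instances against the fully loop-based evaluation
  for (seed in 1:4) {
    m <- sample(4:6, 1)
    mats <- list(featureValues(randomOmics(m, 7, seed = seed)),
                 featureValues(randomOmics(m, 5, seed = seed + 100)))
    om <- lapply(seq_along(mats), function(i)
      OmicsMatrix(mats[[i]], datatype = paste0("d", i)))
    zPkg <- featureValues(ibfe(om, variant = "ibfe1"))
    zOracle <- loopIbfe(mats)
    expect_equal(unname(zPkg), zOracle, tolerance = 1e-10)
  }
})

test_that("integrated similarity is symmetric, unit-diagonal and bounded", {
  for (seed in 1:5) {
    ds <- list(randomOmics(8, 12, seed = seed),
               randomOmics(8, 5, seed = seed + 50))
    z <- featureValues(ibfe(ds, variant = sample(c("ibfe1", "ibfe2", "ibfe3"), 1)))
    expect_equal(z, t(z))
    expect_equal(unname(diag(z)), rep(1, 8))
    expect_true(all(abs(z) <= 1))
  }
})

test_that("Spearman-only integration is invariant to increasing transforms", {
  ds <- list(randomOmics(10, 15, seed = 3), randomOmics(10, 9, seed = 4))
  z0 <- featureValues(ibfe(ds, variant = "ibfe3"))
  warped <- list(
    OmicsMatrix(exp(2 * featureValues(ds[[1]])), datatype = "d1"),
    OmicsMatrix(featureValues(ds[[2]])^3 + 5 * featureValues(ds[[2]]),
                datatype = "d2"))
  z1 <- featureValues(ibfe(warped, variant = "ibfe3"))
  expect_equal(unname(z0), unname(z1), tolerance = 1e-12)
})

test_that("permuting patients permutes the integrated similarity identically", {
  ds <- list(randomOmics(7, 10, seed = 5), randomOmics(7, 8, seed = 6))
  z <- featureValues(ibfe(ds))
  set.seed(9); perm <- sample(7)
  dsPerm <- lapply(ds, function(d)
    OmicsMatrix(featureValues(d)[perm, ], datatype = datatypeLabel(d)))
  zPerm <- featureValues(ibfe(dsPerm))
  expect_equal(unname(zPerm), unname(z[perm, perm]), tolerance = 1e-12)
})

test_that("replicated datatypes collapse to the single-datatype result", {
  d <- randomOmics(8, 10, seed = 12)
  z1 <- featureValues(ibfe(list(d), variant = "ibfe2"))
  z3 <- featureValues(ibfe(list(d, d, d), variant = "ibfe2"))
  expect_equal(z1, z3, tolerance = 1e-12)
})

test_that("direct concatenation preserves columns and order", {
  a <- randomOmics(10, 100, seed = 21, datatype = "meth")
  b <- randomOmics(10, 100, seed = 22, datatype = "mrna")
  cc <- directConcatenate(list(a, b))
  expect_equal(dim(featureValues(cc)), c(10, 200))
  expect_equal(unname(featureValues(cc)[, 101]),
               unname(featureValues(b)[, 1]))
  one <- directConcatenate(list(a))
  expect_equal(unname(featureValues(one)), unname(featureValues(a)))
  expect_error(directConcatenate(list()), "empty")
  expect_error(ibfe(list()), "empty")
})
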