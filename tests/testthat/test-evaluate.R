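# Metric suite: pairwise class statistics, clustering agreement, LOO accuracy.

test_that("intra/inter-class correlation means match pairwise enumeration", {
  set.seed(1)
  F <- matrix(rnorm(4 * 6), 4, 6)
  labels <- c(1, 1, 2, 2)
  res <- intraInterPCC(F, labels)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  vals <- vapply(pairs, function(pr) loopPearson(F[pr[1], ], F[pr[2], ]), 0)
  same <- vapply(pairs, function(pr) labels[pr[1]] == labels[pr[2]], NA)
  expect_equal(res$intra, mean(vals[same]), tolerance = 1e-12)
  expect_equal(res$inter, mean(vals[!same]), tolerance = 1e-12)
})

test_that("class-consistent rows give intra near 1 and inter near 0", {
  set.seed(2)
  protoA <- rnorm(200); protoB <- rnorm(200)
  F <- rbind(protoA + rnorm(200, sd = .01), protoA + rnorm(200, sd = .01),
             protoB + rnorm(200, sd = .01), protoB + rnorm(200, sd = .01))
  res <- intraInterPCC(F, c(1, 1, 2, 2))
  expect_gt(res$intra, 0.99)
  expect_lt(abs(res$inter), 0.2)
  expect_error(intraInterPCC(F, c(1, 1, 1, 1)), "two classes")
})

test_that("Gaussian-kernel similarity follows the closed form and conventions", {
  # 3 collinear points with known distances; fixed bandwidth
  F <- matrix(c(0, 0.5, 2), ncol = 1)
  g <- gaussianKernelSimilarity(F, c(1, 1, 2), sigma = 1)
  expect_equal(g$intra, exp(-0.5^2 / 2), tolerance = 1e-12)
  expect_equal(g$inter, mean(exp(-c(2, 1.5)^2 / 2)), tolerance = 1e-12)
  # default bandwidth is the median off-diagonal distance
  g2 <- gaussianKernelSimilarity(F, c(1, 1, 2))
  expect_equal(g2$sigma, 1.5)
  # duplicate points are maximally similar; all-identical warns and returns 1
  F2 <- matrix(rep(1, 8), 4, 2)
  expect_warning(g3 <- gaussianKernelSimilarity(F2, c(1, 1, 2, 2)), "identical")
  expect_equal(g3$intra, 1)
  expect_equal(g3$inter, 1)
})

test_that("restart-selected k-means recovers separable blobs deterministically", {
  set.seed(3)
  F <- rbind(matrix(rnorm(40, mean = 0, sd = .2), 20, 2),
             matrix(rnorm(40, mean = 5, sd = .2), 20, 2))
  truth <- rep(1:2, each = 20)
  a <- bestKmeans(F, 2, nRestarts = 25, seed = 7)
  expect_equal(nmi(truth, a$cluster), 1)
  b <- bestKmeans(F, 2, nRestarts = 25, seed = 7)
  expect_identical(a, b)
  # more restarts from the same stream can only improve the objective
  set.seed(4)
  Fhard <- matrix(rnorm(60 * 4), 60, 4)
  objSmall <- bestKmeans(Fhard, 5, nRestarts = 5, seed = 11)$objective
  objLarge <- bestKmeans(Fhard, 5, nRestarts = 50, seed = 11)$objective
  expect_lte(objLarge, objSmall)
  expect_error(bestKmeans(F, 41, nRestarts = 2, seed = 1), "k must")
})

test_that("normalized mutual information matches the entropy oracle and its conventions", {
  expect_equal(nmi(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)   # independent 2x2 table
  set.seed(5)
  for (i in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(nmi(a, b), loopNMI(a, b), tolerance = 1e-12)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)        # symmetry
    expect_equal(nmi(a, b), nmi(4 - a, letters[b]), tolerance = 1e-12) # renaming
  }
  # zero-entropy conventions
  expect_equal(nmi(rep(1, 5), rep(2, 5)), 1)
  expect_equal(nmi(rep(1, 5), c(1, 1, 1, 2, 2)), 0)
  expect_error(nmi(1:3, 1:4), "equal length")
})

test_that("leave-one-out random forest is accurate when classes separate and at chance otherwise", {
  set.seed(6)
  F <- rbind(matrix(rnorm(15 * 10, mean = 0), 15, 10),
             matrix(rnorm(15 * 10, mean = 3), 15, 10))
  truth <- rep(1:2, each = 15)
  expect_gte(looRFAccuracy(F, truth, numTrees = 100, seed = 1), 0.95)
  # same features, permuted labels: accuracy near 0.5
  set.seed(7)
  shuffled <- sample(truth)
  accNull <- looRFAccuracy(F, shuffled, numTrees = 100, seed = 2)
  expect_lt(abs(accNull - 0.5), 0.3)
  expect_error(looRFAccuracy(F, rep(1, 30)), "two classes")
})

test_that("stability selection recovers the planted number of clusters", {
  # equilateral blob layout: any 2-cluster merge is ambiguous across
  # restarts, while the 3-cluster solution is unique and stable
  set.seed(8)
  centers <- rbind(c(0, 0), c(10, 0), c(5, 8.66))
  F <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(24, mean = rep(centers[g, ], each = 12), sd = .3), 12, 2)))
  sk <- stableK(F, kRange = 2:5, nRestarts = 20, nBatches = 6, seed = 1)
  expect_equal(sk$k, 3)
  expect_equal(unname(sk$stability["3"]), 1)   # identical batch winners
  expect_equal(nmi(rep(1:3, each = 12), sk$cluster), 1)
})

test_that("the benchmark runner reports every method-metric pair with mean and sd", {
  rep1 <- runBenchmark("sd2", methods = c("data1", "concatenation", "ibfe2"),
                       nRepeats = 2, seed = 3, q = 0.5,
                       metrics = c("pcc", "nmi"), kmRestarts = 10,
                       nPerBlock = 10, nVars = 20)
  s <- reportSummary(rep1)
  expect_equal(nrow(s), 3 * 3)           # 3 methods x (2 pcc + 1 nmi) metrics
  expect_true(all(c("mean", "sd", "n") %in% names(s)))
  expect_equal(reportConfig(rep1)$seed, 3)
  # single repeat: sd reported as zero
  rep2 <- runBenchmark("sd2", methods = "data1", nRepeats = 1, seed = 4,
                       q = 0.5, metrics = "pcc", nPerBlock = 10, nVars = 20)
  expect_true(all(reportSummary(rep2)$sd == 0))
  # determinism of the full run
  rep3 <- runBenchmark("sd2", methods = "data1", nRepeats = 1, seed = 4,
                       q = 0.5, metrics = "pcc", nPerBlock = 10, nVars = 20)
  expect_identical(reportSummary(rep2), reportSummary(rep3))
})

test_that("unclassified patients are excluded from label-dependent metrics", {
  sim <- realisticAugment(simulateScenario("sd2", q = 0.3, seed = 21,
                                           nPerBlock = 10, nVars = 10))
  lab <- trueLabels(sim)
  F <- featureValues(directConcatenate(simDatasets(sim)))
  res <- intraInterPCC(F, lab)
  resClassified <- intraInterPCC(F[!is.na(lab), ], lab[!is.na(lab)])
  expect_equal(res$intra, resClassified$intra, tolerance = 1e-12)
  expect_equal(res$inter, resClassified$inter, tolerance = 1e-12)
})
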