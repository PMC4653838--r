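# Metric suite and repeated-simulation benchmark runner.

.asFeatureMatrix <- function(F) {
  if (is(F, "OmicsMatrix") || is(F, "SimilarityMatrix") ||
      is(F, "StackedFeatureMatrix")) F <- featureValues(F)
  F <- as.matrix(F)
  if (!all(is.finite(F))) stop("feature matrix contains non-finite values")
  F
}

.pairMasks <- function(labels, m) {
  keep <- !is.na(labels)
  same <- outer(labels, labels, "==")
  same[!keep, ] <- NA; same[, !keep] <- NA
  ut <- upper.tri(matrix(0, m, m))
  list(intra = ut & !is.na(same) & same, inter = ut & !is.na(same) & !same)
}

#' Intra/inter-class mean pairwise Pearson correlation
#'
#' Measures class consistency and discrimination of a feature
#' representation: the Pearson correlation between every unordered pair of
#' patients' feature rows, averaged separately over same-class and
#' different-class pairs (diagonal excluded; `NA` labels excluded).
#'
#' @param F feature representation: numeric matrix with patients as rows,
#'   or any package matrix class (for the integrated method, the rows of
#'   the similarity matrix Z are the features).
#' @param labels class label per patient (`NA` = excluded).
#' @return named list with `intra` and `inter` means.
#' @export
intraInterPCC <- function(F, labels) {
  F <- .asFeatureMatrix(F)
  stopifnot(length(labels) == nrow(F))
  if (length(unique(stats::na.omit(labels))) < 2)
    stop("at least two classes are required")
  R <- .rowCorrelation(F, "pearson")
  mk <- .pairMasks(labels, nrow(F))
  list(intra = mean(R[mk$intra]), inter = mean(R[mk$inter]))
}

#' Intra/inter-class mean Gaussian-kernel similarity
#'
#' Same averaging as [intraInterPCC()] but with similarity
#' `exp(-d^2 / (2 sigma^2))` for Euclidean distance `d`. The bandwidth
#' defaults to the median off-diagonal pairwise distance, a standard
#' heuristic; when all points coincide (`sigma = 0`) every similarity is
#' defined as 1 and a warning is emitted.
#'
#' @inheritParams intraInterPCC
#' @param sigma kernel bandwidth; `NULL` for the median heuristic.
#' @return named list with `intra`, `inter` and the `sigma` used.
#' @export
gaussianKernelSimilarity <- function(F, labels, sigma = NULL) {
  F <- .asFeatureMatrix(F)
  stopifnot(length(labels) == nrow(F))
  if (length(unique(stats::na.omit(labels))) < 2)
    stop("at least two classes are required")
  D <- as.matrix(stats::dist(F))
  if (is.null(sigma)) sigma <- stats::median(D[upper.tri(D)])
  if (sigma == 0) {
    warning("all points identical (sigma = 0); similarity defined as 1 everywhere")
    K <- matrix(1, nrow(F), nrow(F))
  } else K <- exp(-D^2 / (2 * sigma^2))
  mk <- .pairMasks(labels, nrow(F))
  list(intra = mean(K[mk$intra]), inter = mean(K[mk$inter]), sigma = sigma)
}

#' Best-of-restarts k-means
#'
#' Runs k-means with `nRestarts` random initializations and keeps the
#' partition with the minimum total within-cluster sum of point-to-centroid
#' squared distances. Deterministic given `seed`.
#'
#' @inheritParams intraInterPCC
#' @param k number of clusters (`2 <= k <` number of patients).
#' @param nRestarts number of random restarts (1000 for full runs; smaller
#'   values are adequate for quick checks).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list with `cluster` (integer vector) and `objective` (the
#'   minimized total within-cluster sum of squares).
#' @export
bestKmeans <- function(F, k, nRestarts = 1000L, seed = NULL) {
  F <- .asFeatureMatrix(F)
  if (k < 2 || k >= nrow(F)) stop("k must satisfy 2 <= k < number of patients")
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  km <- suppressWarnings(stats::kmeans(F, centers = k, nstart = nRestarts,
                                       iter.max = 100L))
  list(cluster = stats::setNames(as.integer(km$cluster), rownames(F)),
       objective = km$tot.withinss)
}

#' Normalized mutual information between two partitions
#'
#' `I(A;B)` normalized by `sqrt(H(A) * H(B))` (default) or by
#' `max(H(A), H(B))`. When either partition has zero entropy (a single
#' cluster) the value is 1 if the partitions are identical and 0 otherwise.
#' Symmetric and invariant to label renaming.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @param normalization `"sqrt"` or `"max"`.
#' @return value in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
nmi <- function(a, b, normalization = c("sqrt", "max")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("label vectors must have equal length")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("no jointly labeled observations")
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij); pb <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pa); hb <- ent(pb)
  if (ha == 0 || hb == 0) {
    identical_part <- identical(as.integer(factor(a)), as.integer(factor(b)))
    return(if (identical_part) 1 else 0)
  }
  pout <- outer(pa, pb)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / pout[nz]))
  denom <- if (normalization == "sqrt") sqrt(ha * hb) else max(ha, hb)
  min(max(mi / denom, 0), 1)
}

#' Leave-one-out random-forest classification accuracy
#'
#' For each labeled patient, a random forest is trained on all other
#' patients and the held-out one is predicted; the accuracy is the fraction
#' of correct predictions. `NA`-labeled patients are excluded entirely.
#'
#' @inheritParams intraInterPCC
#' @param numTrees number of trees per forest (default 500).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param seed integer seed; each fold uses a deterministic derived seed.
#' @return accuracy in \[0, 1\].
#' @export
looRFAccuracy <- function(F, labels, numTrees = 500L, mtry = NULL, seed = 1L) {
  F <- .asFeatureMatrix(F)
  stopifnot(length(labels) == nrow(F))
  keep <- !is.na(labels)
  F <- F[keep, , drop = FALSE]
  y <- factor(labels[keep])
  if (nlevels(y) < 2) stop("at least two classes are required")
  if (nrow(F) < 10) stop("too few patients for leave-one-out evaluation")
  if (is.null(colnames(F))) colnames(F) <- paste0("f", seq_len(ncol(F)))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(F))))
  correct <- vapply(seq_len(nrow(F)), function(i) {
    fit <- ranger::ranger(x = F[-i, , drop = FALSE], y = droplevels(y[-i]),
                          num.trees = numTrees, mtry = mtry,
                          seed = as.integer((seed + i) %% .Machine$integer.max),
                          num.threads = 1L, verbose = FALSE)
    pred <- stats::predict(fit, data = F[i, , drop = FALSE],
                           num.threads = 1L)$predictions
    as.character(pred) == as.character(y[i])
  }, NA)
  mean(correct)
}

#' Stability-based choice of the number of clusters
#'
#' For each candidate `k`, the restart protocol of [bestKmeans()] is run in
#' `nBatches` independent batches, each on a random subsample of
#' `subsample` of the patients, and the stability of `k` is scored as the
#' mean pairwise normalized mutual information among the batch-winning
#' partitions (computed on the patients two batches share). A `k` whose
#' partition reflects real structure survives subsampling; an arbitrary
#' merge or split flips between near-tied optima and scores low. The most
#' stable `k` (ties broken toward the smaller `k`) is returned together
#' with its full-cohort best-of-restarts partition. This is the protocol
#' used on real cohorts, where no ground-truth labels exist.
#'
#' @inheritParams bestKmeans
#' @param kRange candidate cluster counts (default `2:10`).
#' @param nBatches independent subsampled batches per `k` (default 10).
#' @param subsample fraction of patients drawn (without replacement) per
#'   batch.
#' @return list with `k`, `cluster` (full-cohort partition at the selected
#'   `k`), and `stability` (named vector of scores per candidate `k`).
#' @export
stableK <- function(F, kRange = 2:10, nRestarts = 1000L, nBatches = 10L,
                    seed = 1L, subsample = 0.8) {
  F <- .asFeatureMatrix(F)
  m <- nrow(F)
  kRange <- kRange[kRange >= 2 & kRange < floor(subsample * m)]
  if (!length(kRange)) stop("no admissible k in kRange")
  scores <- numeric(length(kRange))
  best <- vector("list", length(kRange))
  for (j in seq_along(kRange)) {
    k <- kRange[j]
    runs <- lapply(seq_len(nBatches), function(b) {
      set.seed(as.integer((seed + 1000L * k + b) %% .Machine$integer.max))
      idx <- sort(sample.int(m, ceiling(subsample * m)))
      cl <- bestKmeans(F[idx, , drop = FALSE], k, nRestarts = nRestarts)$cluster
      stats::setNames(cl, if (is.null(rownames(F))) as.character(idx)
                          else rownames(F)[idx])
    })
    pairs <- utils::combn(nBatches, 2)
    scores[j] <- mean(apply(pairs, 2, function(pr) {
      shared <- intersect(names(runs[[pr[1]]]), names(runs[[pr[2]]]))
      nmi(runs[[pr[1]]][shared], runs[[pr[2]]][shared])
    }))
    best[[j]] <- bestKmeans(F, k, nRestarts = nRestarts,
                            seed = seed + 7919L * k)$cluster
  }
  jBest <- which.max(scores)  # first maximum = smallest k on ties
  list(k = kRange[jBest], cluster = best[[jBest]],
       stability = stats::setNames(scores, kRange))
}

.METHODS <- c("data1", "data2", "concatenation", "ibfe1", "ibfe2", "ibfe3")

.methodFeatures <- function(method, datasets) {
  switch(method,
    data1 = featureValues(datasets[[1]]),
    data2 = featureValues(datasets[[2]]),
    concatenation = featureValues(directConcatenate(datasets)),
    featureValues(ibfe(datasets, variant = method)))
}

#' Repeated-simulation benchmark of integration methods
#'
#' Repeats a simulation scenario `nRepeats` times; in each repeat, builds
#' the feature representation of every requested method (raw single
#' datatypes, direct concatenation, or the rows of the integrated
#' similarity matrix), computes the requested metric families against the
#' planted labels, and reports mean and standard deviation per method and
#' metric. Unclassified patients (realistic mode) participate in clustering
#' but are excluded from every label-dependent score.
#'
#' @inheritParams simulateScenario
#' @param methods subset of `data1`, `data2`, `concatenation`, `ibfe1`,
#'   `ibfe2`, `ibfe3`.
#' @param nRepeats number of independent simulation repeats (100 for full
#'   runs).
#' @param metrics metric families to compute: `"pcc"`, `"kernel"`, `"nmi"`,
#'   `"rf"`.
#' @param k number of clusters for the k-means metric; defaults to the
#'   scenario's true class count (2 for sd1-sd4, 4 for sd5).
#' @param kmRestarts k-means restarts per repeat.
#' @param numTrees random-forest trees for the leave-one-out metric.
#' @param seed master seed; repeat `r` uses `seed + r - 1`.
#' @return An [EvaluationReport-class].
#' @export
runBenchmark <- function(scenario, methods = c("concatenation", "ibfe1"),
                         nRepeats = 100L, seed = 1L, q = 1,
                         sigmaPair = c(0.5, 2), realistic = FALSE,
                         metrics = c("pcc", "kernel", "nmi", "rf"),
                         k = NULL, kmRestarts = 1000L, numTrees = 500L,
                         nPerBlock = 50L, nVars = 100L) {
  methods <- match.arg(methods, .METHODS, several.ok = TRUE)
  metrics <- match.arg(metrics, c("pcc", "kernel", "nmi", "rf"), several.ok = TRUE)
  if (is.null(k)) k <- if (scenario == "sd5") 4L else 2L
  rows <- list()
  for (r in seq_len(nRepeats)) {
    sim <- simulateScenario(scenario, q = q, sigmaPair = sigmaPair,
                            realistic = realistic, seed = seed + r - 1L,
                            nPerBlock = nPerBlock, nVars = nVars)
    labels <- trueLabels(sim)
    for (method in methods) {
      F <- .methodFeatures(method, simDatasets(sim))
      vals <- c()
      if ("pcc" %in% metrics) {
        p <- intraInterPCC(F, labels)
        vals <- c(vals, pcc_intraclass = p$intra, pcc_interclass = p$inter)
      }
      if ("kernel" %in% metrics) {
        g <- gaussianKernelSimilarity(F, labels)
        vals <- c(vals, sim_intraclass = g$intra, sim_interclass = g$inter)
      }
      if ("nmi" %in% metrics) {
        cl <- bestKmeans(F, k, nRestarts = kmRestarts,
                         seed = seed + 7919L * r)$cluster
        vals <- c(vals, nmi_kmeans = nmi(labels, cl))
      }
      if ("rf" %in% metrics)
        vals <- c(vals, acc_rfloo = looRFAccuracy(F, labels,
                                                  numTrees = numTrees,
                                                  seed = seed + 104729L * r))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, method = method, metric = names(vals), value = unname(vals),
        stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ method + metric, detail,
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1) stats::sd(v) else 0))
  summary <- data.frame(method = agg$method, metric = agg$metric,
                        mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                        n = nRepeats, stringsAsFactors = FALSE)
  new("EvaluationReport", summary = summary, detail = detail,
      config = list(scenario = scenario, methods = methods,
                    nRepeats = nRepeats, seed = seed, q = q,
                    sigmaPair = sigmaPair, realistic = realistic,
                    metrics = metrics, k = k, kmRestarts = kmRestarts,
                    numTrees = numTrees, nPerBlock = nPerBlock,
                    nVars = nVars))
}
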