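# Two-stage correlation-based feature extraction:
#   Stage I  : per-datatype patient-similarity by Pearson/Spearman correlation
#   Stage II : column-wise stacking of the similarity matrices
#   Stage III: Pearson correlation of the stacked rows -> integrated similarity

# Row-wise correlation with well-defined output for zero-variance rows:
# pairs involving a constant row get similarity 0, the diagonal stays 1.
.rowCorrelation <- function(X, method) {
  if (ncol(X) < 2)
    stop("at least 2 feature columns are required to correlate patient rows")
  if (!all(is.finite(X)))
    stop("input contains non-finite values")
  zeroVar <- apply(X, 1L, function(r) max(r) == min(r))
  R <- suppressWarnings(stats::cor(t(X), method = method))
  if (any(zeroVar)) {
    warning(sprintf("%d patient row(s) with zero variance; their pairwise similarities are set to 0",
                    sum(zeroVar)))
    R[zeroVar, ] <- 0
    R[, zeroVar] <- 0
  }
  R[is.na(R)] <- 0
  diag(R) <- 1
  R[] <- pmin(pmax(R, -1), 1)
  dimnames(R) <- list(rownames(X), rownames(X))
  R
}

#' @rdname correlationSimilarity
#' @export
setMethod("correlationSimilarity", "OmicsMatrix", function(x, method = c("pearson", "spearman"), ...) {
  method <- match.arg(method)
  new("SimilarityMatrix", values = .rowCorrelation(x@assay, method),
      method = method)
})

#' @rdname correlationSimilarity
#' @export
setMethod("correlationSimilarity", "matrix", function(x, method = c("pearson", "spearman"), ...) {
  method <- match.arg(method)
  if (is.null(rownames(x))) rownames(x) <- paste0("p", seq_len(nrow(x)))
  new("SimilarityMatrix", values = .rowCorrelation(x, method), method = method)
})

#' Stack similarity matrices column-wise
#'
#' Second integration stage: the per-datatype similarity matrices are
#' concatenated horizontally, in the supplied order, into one
#' patients x (M * K') feature matrix. Entries are already bounded in
#' \[-1, 1\], so no rescaling is applied.
#'
#' @param sims list of [SimilarityMatrix-class] objects sharing identical
#'   patient identifiers in identical order.
#' @param datatypes optional character vector naming the datatype each
#'   similarity matrix came from (recycled into the block index).
#' @return A [StackedFeatureMatrix-class].
#' @examples
#' x <- OmicsMatrix(matrix(rnorm(20), 4, 5,
#'   dimnames = list(paste0("p", 1:4), NULL)))
#' y <- stackFeatures(list(correlationSimilarity(x, "pearson"),
#'                         correlationSimilarity(x, "spearman")))
#' dim(featureValues(y))
#' @export
stackFeatures <- function(sims, datatypes = NULL) {
  if (!length(sims)) stop("no similarity matrices supplied")
  if (!all(vapply(sims, is, TRUE, "SimilarityMatrix")))
    stop("all elements must be SimilarityMatrix objects")
  ids <- patientIDs(sims[[1]])
  for (s in sims[-1])
    if (!identical(patientIDs(s), ids))
      stop("patient identifiers differ between similarity matrices; align patients first")
  if (is.null(datatypes)) datatypes <- paste0("data", seq_along(sims))
  vals <- do.call(cbind, lapply(sims, featureValues))
  m <- length(ids)
  idx <- data.frame(
    block = rep(seq_along(sims), each = m),
    datatype = rep(datatypes, each = m),
    kind = rep(vapply(sims, simMethod, ""), each = m),
    stringsAsFactors = FALSE)
  colnames(vals) <- paste(idx$datatype, idx$kind, rep(ids, length(sims)), sep = ".")
  new("StackedFeatureMatrix", values = vals, blockIndex = idx)
}

#' Integrate stacked similarity features into the final similarity matrix
#'
#' Third integration stage: the integrated similarity of two patients is the
#' Pearson correlation of their rows in the stacked feature matrix. No
#' preprocessing is applied beforehand; the correlation itself centers and
#' scales, which keeps the whole pipeline parameter-free.
#'
#' @param y a [StackedFeatureMatrix-class] (or plain numeric matrix) with at
#'   least 2 columns.
#' @return A [SimilarityMatrix-class] with method `"integrated"`.
#' @export
integrateFeatures <- function(y) {
  vals <- if (is(y, "StackedFeatureMatrix")) y@values else as.matrix(y)
  if (is.null(rownames(vals))) rownames(vals) <- paste0("p", seq_len(nrow(vals)))
  new("SimilarityMatrix", values = .rowCorrelation(vals, "pearson"),
      method = "integrated")
}

.VARIANTS <- list(
  ibfe1 = c("pearson", "spearman"),
  ibfe2 = "pearson",
  ibfe3 = "spearman")

#' Integrated patient similarity from multiple omics datatypes
#'
#' Runs the full two-stage correlation pipeline: per-datatype
#' patient-similarity matrices (Pearson and/or Spearman depending on the
#' variant) are stacked and the Pearson correlation of the stacked rows is
#' returned as the integrated patient-similarity matrix Z. The rows of Z are
#' the extracted features used downstream for clustering and classification.
#'
#' @param datasets list of [OmicsMatrix-class] objects, all restricted to
#'   the same patients in the same order (see [alignPatients()]).
#' @param variant `"ibfe1"` (Pearson + Spearman, the default), `"ibfe2"`
#'   (Pearson only) or `"ibfe3"` (Spearman only; invariant under strictly
#'   increasing per-datatype transforms, the mechanism of scale robustness).
#' @return A [SimilarityMatrix-class] with method `"integrated"`.
#' @examples
#' sim <- simulateScenario("sd1", q = 20, seed = 1)
#' z <- ibfe(simDatasets(sim), variant = "ibfe1")
#' z
#' @export
ibfe <- function(datasets, variant = c("ibfe1", "ibfe2", "ibfe3")) {
  variant <- match.arg(variant)
  if (!length(datasets)) stop("empty dataset list")
  if (!all(vapply(datasets, is, TRUE, "OmicsMatrix")))
    stop("all datasets must be OmicsMatrix objects")
  ids <- patientIDs(datasets[[1]])
  for (d in datasets[-1])
    if (!identical(patientIDs(d), ids))
      stop("datasets are not aligned on the same patients; run alignPatients() first")
  kinds <- .VARIANTS[[variant]]
  sims <- list(); dts <- character()
  for (d in datasets) for (k in kinds) {
    sims[[length(sims) + 1L]] <- correlationSimilarity(d, k)
    dts <- c(dts, datatypeLabel(d))
  }
  integrateFeatures(stackFeatures(sims, datatypes = dts))
}

#' Direct concatenation baseline
#'
#' Concatenates the raw feature columns of all datatypes into one matrix,
#' the most naive integration strategy and the baseline the correlation
#' pipeline is compared against. Feature identifiers are prefixed with the
#' datatype label to stay unique.
#'
#' @param datasets list of [OmicsMatrix-class] objects aligned on the same
#'   patients in the same order.
#' @return An [OmicsMatrix-class] whose columns are all datatypes' columns.
#' @export
directConcatenate <- function(datasets) {
  if (!length(datasets)) stop("empty dataset list")
  if (!all(vapply(datasets, is, TRUE, "OmicsMatrix")))
    stop("all datasets must be OmicsMatrix objects")
  ids <- patientIDs(datasets[[1]])
  for (d in datasets[-1])
    if (!identical(patientIDs(d), ids))
      stop("datasets are not aligned on the same patients; run alignPatients() first")
  mats <- lapply(datasets, function(d) {
    m <- d@assay
    colnames(m) <- paste(d@datatype, colnames(m), sep = ".")
    m
  })
  OmicsMatrix(do.call(cbind, mats), datatype = "concatenation")
}
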