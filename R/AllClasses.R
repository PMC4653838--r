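.SYM_TOL <- 1e-8

#' OmicsMatrix: one datatype's patients-by-features matrix
#'
#' Container for a single omics datatype measured on a cohort: a numeric
#' matrix with patients as rows and molecular features (CpG probes, genes,
#' miRNAs, ...) as columns. Patient identifiers live in the rownames and
#' must be unique; all values must be finite.
#'
#' @slot assay numeric matrix, patients x features, with rownames (patient
#'   identifiers) and colnames (feature identifiers).
#' @slot datatype single character string naming the datatype, e.g.
#'   `"methylation"`; used to keep feature identifiers unique when
#'   concatenating datatypes.
#'
#' @seealso [OmicsMatrix()] for the user-facing constructor,
#'   [correlationSimilarity()], [directConcatenate()].
#' @exportClass OmicsMatrix
setClass("OmicsMatrix",
  representation(assay = "matrix", datatype = "character"))

setValidity("OmicsMatrix", function(object) {
  a <- object@assay
  msg <- character()
  if (!is.numeric(a)) msg <- c(msg, "assay must be numeric")
  if (is.null(rownames(a)) || anyNA(rownames(a)) || any(rownames(a) == ""))
    msg <- c(msg, "patient identifiers (rownames) are required and must be non-empty")
  if (anyDuplicated(rownames(a)))
    msg <- c(msg, sprintf("duplicated patient identifier(s): %s",
      paste(unique(rownames(a)[duplicated(rownames(a))]), collapse = ", ")))
  if (nrow(a) < 3) msg <- c(msg, "at least 3 patients are required")
  if (ncol(a) < 2) msg <- c(msg, "at least 2 feature columns are required")
  if (is.numeric(a) && !all(is.finite(a)))
    msg <- c(msg, "assay contains non-finite values (NA/NaN/Inf)")
  if (length(object@datatype) != 1L)
    msg <- c(msg, "datatype must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric patients x features matrix.
#' @param patientIDs optional character vector of patient identifiers;
#'   defaults to `rownames(values)`.
#' @param featureIDs optional character vector of feature identifiers;
#'   defaults to `colnames(values)`, or `f1, f2, ...` when absent.
#' @param datatype datatype label, e.g. `"mrna"`.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' x <- OmicsMatrix(matrix(rnorm(12), 3, 4,
#'   dimnames = list(c("p1", "p2", "p3"), NULL)), datatype = "toy")
#' patientIDs(x)
#' @export
OmicsMatrix <- function(values, patientIDs = rownames(values),
                        featureIDs = colnames(values), datatype = "data") {
  values <- as.matrix(values)
  if (is.null(featureIDs)) featureIDs <- paste0("f", seq_len(ncol(values)))
  dimnames(values) <- list(patientIDs, featureIDs)
  new("OmicsMatrix", assay = values, datatype = datatype)
}

#' SimilarityMatrix: square patient-by-patient similarity
#'
#' Symmetric matrix of pairwise patient similarity with entries in
#' \[-1, 1\] and unit diagonal, produced either by row-wise correlation of a
#' single datatype (`method` `"pearson"`/`"spearman"`) or by the second
#' integration stage (`method` `"integrated"`).
#'
#' @slot values numeric M x M matrix with identical row/column names.
#' @slot method one of `"pearson"`, `"spearman"`, `"integrated"`.
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(values = "matrix", method = "character"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "similarity matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column patient identifiers must be present and identical")
  if (!all(is.finite(v))) msg <- c(msg, "non-finite similarity values")
  else {
    if (max(abs(v - t(v))) > .SYM_TOL) msg <- c(msg, "matrix is not symmetric")
    if (max(abs(v)) > 1 + .SYM_TOL) msg <- c(msg, "entries outside [-1, 1]")
    if (max(abs(diag(v) - 1)) > .SYM_TOL) msg <- c(msg, "diagonal entries must equal 1")
  }
  if (!object@method %in% c("pearson", "spearman", "integrated"))
    msg <- c(msg, "method must be 'pearson', 'spearman' or 'integrated'")
  if (length(msg)) msg else TRUE
})

#' Construct a SimilarityMatrix
#'
#' @param values square symmetric numeric matrix; entries are clipped to
#'   \[-1, 1\] to absorb floating-point rounding.
#' @param method provenance of the similarity, one of `"pearson"`,
#'   `"spearman"`, `"integrated"`.
#' @return A [SimilarityMatrix-class] object.
#' @export
SimilarityMatrix <- function(values, method = "pearson") {
  values <- as.matrix(values)
  values[] <- pmin(pmax(values, -1), 1)
  new("SimilarityMatrix", values = values, method = method)
}

#' StackedFeatureMatrix: horizontally stacked similarity matrices
#'
#' The intermediate feature space of the two-stage integration: per-datatype
#' similarity matrices concatenated column-wise, so each patient's row holds
#' its similarity profile to every patient under every (datatype,
#' correlation-kind) block. Entries are naturally bounded in \[-1, 1\], so no
#' rescaling is ever applied.
#'
#' @slot values numeric M x C matrix (C = M times the number of stacked
#'   similarity matrices).
#' @slot blockIndex data.frame with one row per column of `values`, columns
#'   `block` (integer), `datatype`, `kind`; records provenance of each column.
#' @exportClass StackedFeatureMatrix
setClass("StackedFeatureMatrix",
  representation(values = "matrix", blockIndex = "data.frame"))

setValidity("StackedFeatureMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v))) msg <- c(msg, "patient identifiers (rownames) required")
  if (nrow(object@blockIndex) != ncol(v))
    msg <- c(msg, "blockIndex must have one row per column")
  if (ncol(v) %% nrow(v) != 0)
    msg <- c(msg, "column count must be a multiple of the patient count")
  if (!all(is.finite(v))) msg <- c(msg, "non-finite values")
  else if (max(abs(v)) > 1 + .SYM_TOL) msg <- c(msg, "entries outside [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' SimulationOutput: generated datatypes plus ground truth
#'
#' Result of one simulation scenario: the observed datatype matrices, the
#' planted cluster labels, the mask of deliberately unclassifiable patients
#' (realistic mode), and the generating parameters.
#'
#' @slot datasets list of [OmicsMatrix-class] objects (two per scenario).
#' @slot trueLabels integer vector of planted class labels, `NA` for
#'   unclassified patients.
#' @slot unclassifiedMask logical vector, `TRUE` for patients whose class is
#'   deliberately undefined.
#' @slot scenario scenario name, `"sd1"` .. `"sd5"`.
#' @slot params list of generator parameters (q, sigmaPair, seed, sizes,
#'   realistic flag).
#' @exportClass SimulationOutput
setClass("SimulationOutput",
  representation(datasets = "list", trueLabels = "integer",
                 unclassifiedMask = "logical", scenario = "character",
                 params = "list"))

setValidity("SimulationOutput", function(object) {
  msg <- character()
  if (!all(vapply(object@datasets, is, TRUE, "OmicsMatrix")))
    msg <- c(msg, "datasets must be OmicsMatrix objects")
  m <- length(object@trueLabels)
  if (length(object@unclassifiedMask) != m)
    msg <- c(msg, "unclassifiedMask length must match trueLabels")
  for (d in object@datasets)
    if (nrow(d@assay) != m) msg <- c(msg, "dataset row count must match labels")
  if (any(is.na(object@trueLabels) != object@unclassifiedMask))
    msg <- c(msg, "NA labels must coincide with the unclassified mask")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: benchmark metrics per method
#'
#' Long-format metric values per repeat (`detail`), their mean and standard
#' deviation per method and metric (`summary`), and the configuration that
#' produced them (`config`).
#'
#' @slot summary data.frame with columns `method`, `metric`, `mean`, `sd`, `n`.
#' @slot detail data.frame with columns `repeat_`, `method`, `metric`, `value`.
#' @slot config list echoing every parameter of the benchmark run.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(summary = "data.frame", detail = "data.frame", config = "list"))

#' SurvivalResult: per-cluster prognosis assessment
#'
#' @slot tests data.frame with one row per cluster: `cluster`, `n` (cluster
#'   size after joining with the clinical table), `nRest`, `chisq` (log-rank
#'   statistic vs all other patients), `p` (chi-square reference, 1 df).
#' @slot curves named list of per-cluster Kaplan-Meier curves (data.frames
#'   from [kmCurve()]).
#' @slot dropped character vector of patient identifiers present in the
#'   labels but absent from the clinical table (or vice versa).
#' @exportClass SurvivalResult
setClass("SurvivalResult",
  representation(tests = "data.frame", curves = "list", dropped = "character"))
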