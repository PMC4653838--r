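#' Accessors for package classes
#'
#' `patientIDs()` returns the ordered patient identifiers; `featureIDs()` the
#' feature identifiers of an [OmicsMatrix-class]; `featureValues()` the
#' underlying numeric matrix (patients as rows) of any matrix-like object in
#' the package; `datatypeLabel()` the datatype tag; `simMethod()` the
#' correlation kind of a [SimilarityMatrix-class]; `blockIndex()` the column
#' provenance of a [StackedFeatureMatrix-class]; `trueLabels()`,
#' `unclassifiedMask()` and `scenarioName()` the ground truth of a
#' [SimulationOutput-class].
#'
#' @param x an object of the corresponding class.
#' @return see the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patientIDs", function(x) standardGeneric("patientIDs"))
#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("datatypeLabel", function(x) standardGeneric("datatypeLabel"))
#' @rdname accessors
#' @export
setGeneric("simMethod", function(x) standardGeneric("simMethod"))
#' @rdname accessors
#' @export
setGeneric("blockIndex", function(x) standardGeneric("blockIndex"))
#' @rdname accessors
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))
#' @rdname accessors
#' @export
setGeneric("unclassifiedMask", function(x) standardGeneric("unclassifiedMask"))
#' @rdname accessors
#' @export
setGeneric("scenarioName", function(x) standardGeneric("scenarioName"))

#' Patient-similarity by row-wise correlation
#'
#' First integration stage: the similarity of every pair of patients is
#' their Pearson or Spearman correlation across the features of one
#' datatype.
#'
#' @param x an [OmicsMatrix-class] or a plain numeric matrix with patients
#'   as rows.
#' @param method `"pearson"` or `"spearman"` (midranks for ties).
#' @param ... passed to methods.
#' @return A [SimilarityMatrix-class].
#' @details A patient row with zero variance has undefined correlation with
#'   every other row; such pairs are assigned similarity 0 (the row's
#'   diagonal entry stays 1) and a warning is emitted.
#' @export
setGeneric("correlationSimilarity",
  function(x, method = c("pearson", "spearman"), ...)
    standardGeneric("correlationSimilarity"))

#' @rdname accessors
#' @export
setMethod("patientIDs", "OmicsMatrix", function(x) rownames(x@assay))
#' @rdname accessors
#' @export
setMethod("patientIDs", "SimilarityMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("patientIDs", "StackedFeatureMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("featureIDs", "OmicsMatrix", function(x) colnames(x@assay))
#' @rdname accessors
#' @export
setMethod("featureValues", "OmicsMatrix", function(x) x@assay)
#' @rdname accessors
#' @export
setMethod("featureValues", "SimilarityMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureValues", "StackedFeatureMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("datatypeLabel", "OmicsMatrix", function(x) x@datatype)
#' @rdname accessors
#' @export
setMethod("simMethod", "SimilarityMatrix", function(x) x@method)
#' @rdname accessors
#' @export
setMethod("blockIndex", "StackedFeatureMatrix", function(x) x@blockIndex)
#' @rdname accessors
#' @export
setMethod("trueLabels", "SimulationOutput", function(x) x@trueLabels)
#' @rdname accessors
#' @export
setMethod("unclassifiedMask", "SimulationOutput", function(x) x@unclassifiedMask)
#' @rdname accessors
#' @export
setMethod("scenarioName", "SimulationOutput", function(x) x@scenario)

#' @describeIn SimulationOutput the list of generated [OmicsMatrix-class] objects
#' @param x a `SimulationOutput`.
#' @export
setGeneric("simDatasets", function(x) standardGeneric("simDatasets"))
#' @rdname SimulationOutput-class
#' @export
setMethod("simDatasets", "SimulationOutput", function(x) x@datasets)

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix '%s': %d patients x %d features\n",
              object@datatype, nrow(object@assay), ncol(object@assay)))
})
setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d x %d patients\n",
              object@method, nrow(object@values), ncol(object@values)))
})
setMethod("show", "StackedFeatureMatrix", function(object) {
  cat(sprintf("StackedFeatureMatrix: %d patients x %d stacked features (%d blocks)\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@blockIndex$block))))
})
setMethod("show", "SimulationOutput", function(object) {
  cat(sprintf("SimulationOutput '%s'%s: %d patients, %d datatypes, %d classes",
              object@scenario,
              if (isTRUE(object@params$realistic)) " (realistic)" else "",
              length(object@trueLabels), length(object@datasets),
              length(unique(stats::na.omit(object@trueLabels)))))
  if (any(object@unclassifiedMask))
    cat(sprintf(", %d unclassified", sum(object@unclassifiedMask)))
  cat("\n")
})
setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d methods x %d metrics over %d repeat(s)\n",
              length(unique(object@summary$method)),
              length(unique(object@summary$metric)),
              object@config$nRepeats))
  print(object@summary, row.names = FALSE)
})
setMethod("show", "SurvivalResult", function(object) {
  cat(sprintf("SurvivalResult: %d cluster(s) tested vs rest\n",
              nrow(object@tests)))
  print(object@tests, row.names = FALSE)
})

#' @describeIn EvaluationReport mean/sd per method and metric
#' @param x an `EvaluationReport`.
#' @export
setGeneric("reportSummary", function(x) standardGeneric("reportSummary"))
#' @rdname EvaluationReport-class
#' @export
setMethod("reportSummary", "EvaluationReport", function(x) x@summary)
#' @describeIn EvaluationReport per-repeat metric values
#' @export
setGeneric("reportDetail", function(x) standardGeneric("reportDetail"))
#' @rdname EvaluationReport-class
#' @export
setMethod("reportDetail", "EvaluationReport", function(x) x@detail)
#' @describeIn EvaluationReport the configuration that produced the report
#' @export
setGeneric("reportConfig", function(x) standardGeneric("reportConfig"))
#' @rdname EvaluationReport-class
#' @export
setMethod("reportConfig", "EvaluationReport", function(x) x@config)

#' @describeIn SurvivalResult per-cluster log-rank tests vs the rest
#' @param x a `SurvivalResult`.
#' @export
setGeneric("survivalTests", function(x) standardGeneric("survivalTests"))
#' @rdname SurvivalResult-class
#' @export
setMethod("survivalTests", "SurvivalResult", function(x) x@tests)
#' @describeIn SurvivalResult per-cluster Kaplan-Meier curves
#' @export
setGeneric("survivalCurves", function(x) standardGeneric("survivalCurves"))
#' @rdname SurvivalResult-class
#' @export
setMethod("survivalCurves", "SurvivalResult", function(x) x@curves)
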