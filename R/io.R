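# Delimited-text readers/writers and patient alignment across datatypes.
# Canonical on-disk layout: patients as rows, first column the patient
# identifier, header row of feature (or patient) identifiers.

.readTable <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 2) stop("expected an identifier column plus data columns in ", path)
  tab
}

#' Read a patients-by-features matrix from delimited text
#'
#' @param path file path; first column patient identifiers, header row of
#'   feature identifiers.
#' @param sep field separator (default tab; use `","` for CSV).
#' @param datatype datatype label to attach.
#' @param transpose set `TRUE` for files exported features-as-rows.
#' @return An [OmicsMatrix-class].
#' @export
readOmicsMatrix <- function(path, sep = "\t", datatype = "data",
                            transpose = FALSE) {
  tab <- .readTable(path, sep)
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated patient identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  dat <- tab[, -1, drop = FALSE]
  for (j in seq_along(dat)) {
    v <- suppressWarnings(as.numeric(dat[[j]]))
    bad <- which(is.na(v) & !is.na(dat[[j]]))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   dat[[j]][bad[1]], bad[1], names(dat)[j], path))
    dat[[j]] <- v
  }
  m <- as.matrix(dat)
  rownames(m) <- ids
  if (transpose) m <- t(m)  # header row held the patient identifiers
  OmicsMatrix(m, datatype = datatype)
}

#' Write a patients-by-features matrix as delimited text
#'
#' @param x an [OmicsMatrix-class] (or any object with [featureValues()]).
#' @param path output file path.
#' @param sep field separator.
#' @param idColumn name for the identifier column header.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(x, path, sep = "\t", idColumn = "patient_id") {
  m <- featureValues(x)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- idColumn
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a square patient-similarity matrix
#'
#' The square layout mirrors [writeOmicsMatrix()]: first column and header
#' both carry the patient identifiers, in matching order.
#'
#' @param path file path.
#' @param sep field separator.
#' @param method similarity provenance tag to attach on reading.
#' @return [SimilarityMatrix-class] (read) or `path` invisibly (write).
#' @export
readSimilarityMatrix <- function(path, sep = "\t", method = "integrated") {
  x <- readOmicsMatrix(path, sep = sep)
  v <- featureValues(x)
  if (!identical(rownames(v), colnames(v)))
    stop("row and column identifiers disagree in ", path)
  SimilarityMatrix(v, method = method)
}

#' @rdname readSimilarityMatrix
#' @param x a [SimilarityMatrix-class].
#' @export
writeSimilarityMatrix <- function(x, path, sep = "\t") {
  writeOmicsMatrix(x, path, sep = sep)
}

#' Read/write cluster labels
#'
#' Two-column table `patient_id`, `cluster`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return named vector of cluster labels (read) or `path` invisibly.
#' @export
readLabels <- function(path, sep = "\t") {
  tab <- .readTable(path, sep)
  stopifnot(all(c("patient_id", "cluster") %in% names(tab)))
  stats::setNames(tab$cluster, as.character(tab$patient_id))
}

#' @rdname readLabels
#' @param labels named vector of cluster labels.
#' @export
writeLabels <- function(labels, path, sep = "\t") {
  utils::write.table(
    data.frame(patient_id = names(labels), cluster = unname(labels)),
    path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Columns `patient_id`, `time` (follow-up duration) and `event`
#' (1 = event observed, 0 = censored).
#'
#' @param path file path.
#' @param sep field separator.
#' @return validated data.frame.
#' @export
readClinical <- function(path, sep = "\t") {
  tab <- .readTable(path, sep)
  stopifnot(all(c("patient_id", "time", "event") %in% names(tab)))
  tab$patient_id <- as.character(tab$patient_id)
  if (anyDuplicated(tab$patient_id)) stop("duplicated patient_id in ", path)
  if (any(tab$time < 0)) stop("negative follow-up time in ", path)
  if (!all(tab$event %in% c(0, 1))) stop("event must be 0 or 1 in ", path)
  tab
}

#' Restrict datatypes to their common patients
#'
#' Integration assumes every datatype covers the same patients; real
#' exports rarely do. This restricts every dataset to the intersection of
#' patient identifiers, in a canonical sorted order, and reports how many
#' patients each datatype lost.
#'
#' @param datasets list of [OmicsMatrix-class] objects.
#' @return list of [OmicsMatrix-class] objects on identical, sorted
#'   patients; errors when the intersection is empty.
#' @export
alignPatients <- function(datasets) {
  if (!length(datasets)) stop("empty dataset list")
  idSets <- lapply(datasets, patientIDs)
  common <- sort(Reduce(intersect, idSets))
  if (!length(common)) stop("no patients shared by all datatypes")
  for (i in seq_along(datasets)) {
    nDrop <- length(idSets[[i]]) - length(common)
    if (nDrop > 0)
      message(sprintf("datatype '%s': dropped %d patient(s) absent elsewhere",
                      datatypeLabel(datasets[[i]]), nDrop))
  }
  lapply(datasets, function(d)
    OmicsMatrix(featureValues(d)[common, , drop = FALSE],
                datatype = datatypeLabel(d)))
}
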