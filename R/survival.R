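# Subtype-prognosis assessment: Kaplan-Meier curves per discovered cluster
# and a log-rank test of each cluster against all remaining patients.

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function at each distinct event
#' time. Ties between events and censorings at the same time follow the
#' standard convention that censoring happens after the events.
#'
#' @param time non-negative follow-up times.
#' @param event event indicator: 1 = event observed, 0 = censored.
#' @return data.frame with columns `time`, `nRisk`, `nEvent`, `surv`
#'   (non-increasing, in \[0, 1\]).
#' @examples
#' kmCurve(c(1, 2, 3), c(1, 1, 1))  # steps 2/3, 1/3, 0
#' @export
kmCurve <- function(time, event) {
  if (length(time) != length(event) || !length(time))
    stop("time and event must be non-empty vectors of equal length")
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
             surv = fit$surv)
}

#' Log-rank test of each cluster versus the remaining patients
#'
#' Joins predicted cluster labels with a clinical table and, for every
#' cluster, performs a two-group log-rank test (cluster vs all other
#' patients) with the chi-square (1 df) reference distribution, plus a
#' Kaplan-Meier curve per cluster. Raw p-values are reported without
#' multiple-testing correction, as is conventional for per-cluster
#' prognosis screens; interpret accordingly when many clusters are tested.
#'
#' @param labels named vector (names = patient identifiers) or data.frame
#'   with columns `patient_id` and `cluster`.
#' @param clinical data.frame with columns `patient_id`, `time` (follow-up,
#'   consistent units) and `event` (1 = event, 0 = censored).
#' @return A [SurvivalResult-class]. Patients present in only one of the
#'   two inputs are dropped and recorded; clusters of size 0 after the join
#'   are skipped with a warning.
#' @export
logrankVsRest <- function(labels, clinical) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("patient_id", "cluster") %in% names(labels)))
    labels <- stats::setNames(labels$cluster, labels$patient_id)
  }
  if (is.null(names(labels))) stop("labels must carry patient identifiers")
  stopifnot(all(c("patient_id", "time", "event") %in% names(clinical)))
  if (anyDuplicated(clinical$patient_id)) stop("duplicated patient_id in clinical table")
  if (any(clinical$time < 0)) stop("negative follow-up time")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0 or 1")

  common <- intersect(names(labels), clinical$patient_id)
  dropped <- c(setdiff(names(labels), common), setdiff(clinical$patient_id, common))
  if (!length(common)) stop("no patients shared between labels and clinical table")
  if (length(dropped))
    message(length(dropped), " patient(s) present in only one input were dropped")
  cl <- clinical[match(common, clinical$patient_id), ]
  grp <- labels[common]

  clusters <- sort(unique(grp))
  tests <- list(); curves <- list()
  for (g in clusters) {
    inG <- grp == g
    if (!any(inG)) { warning("cluster ", g, " empty after join; skipped"); next }
    curves[[as.character(g)]] <- kmCurve(cl$time[inG], cl$event[inG])
    if (all(inG)) { warning("single cluster covers all patients; no test possible"); next }
    sd <- survival::survdiff(survival::Surv(cl$time, cl$event) ~ inG)
    tests[[as.character(g)]] <- data.frame(
      cluster = g, n = sum(inG), nRest = sum(!inG),
      chisq = sd$chisq,
      p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  }
  new("SurvivalResult",
      tests = if (length(tests)) do.call(rbind, tests) else
        data.frame(cluster = character(), n = integer(), nRest = integer(),
                   chisq = numeric(), p = numeric()),
      curves = curves, dropped = as.character(dropped))
}
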