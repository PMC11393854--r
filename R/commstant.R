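COMMSTANT_WINDOW <- c("induction", "consolidation", "maintenance")

#' Classify one patient's CMMC trajectory (coMMstant index)
#'
#' The coMMstant index dichotomizes a patient's on-treatment CMMC
#' trajectory: index `1` for patients whose circulating cells are
#' consistently detectable (count >= 1 at every in-window enumeration),
#' index `0` for patients with at least one undetectable enumeration, and
#' `indeterminate` when fewer than two in-window enumerations exist.
#'
#' Two published phrasings of the rule coexist and differ for series that
#' start positive and hit zero only later (e.g. counts 3, 4, 0):
#' `"all_positive"` (the default, "consistently detectable") assigns index
#' 0 to any series containing a zero, while `"first_two"` assigns index 0
#' only when a zero occurs within the first two in-window enumerations.
#'
#' @param timepoints data.frame of one patient's enumerations with columns
#'   `time_months`, `phase`, `cmmc_count` (extra columns ignored); rows are
#'   sorted by time internally.
#' @param window_phases Phases whose enumerations enter the classification;
#'   default induction, consolidation and maintenance.
#' @param rule `"all_positive"` or `"first_two"` (see Details).
#' @return list of class `commstant_result` with elements `patient_id`,
#'   `index` (`"1"`, `"0"` or `"indeterminate"`), `n_enumerations_used`,
#'   and `window` (phases plus the time span of the used rows).
#' @examples
#' tp <- data.frame(patient_id = "P1", time_months = c(3, 6, 9),
#'                  phase = c("induction", "consolidation", "maintenance"),
#'                  cmmc_count = c(3L, 5L, 2L))
#' classify_commstant(tp)$index  # "1"
#' @export
classify_commstant <- function(timepoints,
                               window_phases = COMMSTANT_WINDOW,
                               rule = c("all_positive", "first_two")) {
  rule <- match.arg(rule)
  timepoints <- as.data.frame(timepoints)
  pid <- if (nrow(timepoints)) unique(timepoints$patient_id) else NA_character_
  if (length(pid) > 1)
    validation_error("classify_commstant expects the timepoints of one patient")
  used <- timepoints[timepoints$phase %in% window_phases, , drop = FALSE]
  used <- used[order(used$time_months), , drop = FALSE]
  n <- nrow(used)
  index <- if (n < 2) {
    "indeterminate"
  } else if (rule == "all_positive") {
    if (all(used$cmmc_count >= 1)) "1" else "0"
  } else {
    if (any(used$cmmc_count[1:2] == 0)) "0" else "1"
  }
  structure(list(patient_id = pid, index = index, n_enumerations_used = n,
                 window = list(phases = window_phases,
                               time_span = if (n) range(used$time_months)
                                           else c(NA_real_, NA_real_))),
            class = "commstant_result")
}

#' @export
print.commstant_result <- function(x, ...) {
  cat(sprintf("coMMstant index %s for %s (%d enumerations used)\n",
              x$index, x$patient_id, x$n_enumerations_used))
  invisible(x)
}

#' Classify every patient in a cohort
#'
#' Applies [classify_commstant()] patient by patient. Patients with fewer
#' than two in-window enumerations come back `indeterminate` and are
#' excluded from downstream group comparisons.
#'
#' @inheritParams classify_commstant
#' @param cohort A [cmmc_cohort()].
#' @return data.frame with columns `patient_id`, `index`, `n_used`.
#' @export
classify_cohort_commstant <- function(cohort,
                                      window_phases = COMMSTANT_WINDOW,
                                      rule = c("all_positive", "first_two")) {
  stopifnot(inherits(cohort, "cmmc_cohort"))
  rule <- match.arg(rule)
  ids <- cohort$patients$patient_id
  if (!length(ids))
    return(data.frame(patient_id = character(), index = character(),
                      n_used = integer(), stringsAsFactors = FALSE))
  res <- lapply(ids, function(id) {
    tp <- cohort$timepoints[cohort$timepoints$patient_id == id, , drop = FALSE]
    r <- classify_commstant(tp, window_phases, rule)
    data.frame(patient_id = id, index = r$index,
               n_used = r$n_enumerations_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Split patients at the median baseline CMMC count
#'
#' Baseline is each patient's earliest enumeration regardless of phase
#' label. The median is the sample median (mean of the two central values
#' for even n) and a patient whose baseline count equals the median is
#' placed in the high group.
#'
#' @param baselines Named numeric vector of baseline counts (names =
#'   patient ids), e.g. from [baseline_counts()].
#' @return list with elements `median`, `high` (patient ids with count >=
#'   median) and `low`.
#' @examples
#' stratify_by_baseline_median(c(a = 22, b = 52, c = 344, d = 24,
#'                               e = 976, f = 327, g = 2463))
#' @export
stratify_by_baseline_median <- function(baselines) {
  if (length(baselines) == 0)
    validation_error("at least one baseline count is required")
  if (is.null(names(baselines)))
    names(baselines) <- paste0("patient_", seq_along(baselines))
  med <- median(baselines)
  list(median = med,
       high = names(baselines)[baselines >= med],
       low = names(baselines)[baselines < med])
}

#' Baseline CMMC count per patient
#'
#' @param cohort A [cmmc_cohort()].
#' @param stages Restrict to these disease stages (default both).
#' @return Named numeric vector: each patient's earliest enumeration count.
#' @export
baseline_counts <- function(cohort, stages = c("SMM", "MM")) {
  stopifnot(inherits(cohort, "cmmc_cohort"))
  keep <- cohort$patients$patient_id[cohort$patients$stage %in% stages]
  tp <- cohort$timepoints[cohort$timepoints$patient_id %in% keep, , drop = FALSE]
  if (!nrow(tp)) return(setNames(numeric(), character()))
  first <- tp[!duplicated(tp$patient_id), , drop = FALSE]  # sorted by time
  setNames(as.numeric(first$cmmc_count), first$patient_id)
}

#' Flow-cytometry-equivalent CMMC percentage
#'
#' Converts an absolute CMMC count (per 4 mL of blood) into the
#' flow-cytometry percentage scale by proportional scaling against one or
#' more calibration pairs of (absolute count, flow percentage) measured on
#' the same samples, averaging across pairs and rounding to two decimals.
#'
#' @param count Non-negative integer CMMC count.
#' @param pairs data.frame with columns `count` (> 0) and `percent` (> 0).
#' @return Percentage, rounded to 2 decimals.
#' @examples
#' flow_equivalent_percentage(349, example_flow_calibration())  # 0.02
#' @export
flow_equivalent_percentage <- function(count, pairs) {
  pairs <- check_columns(as.data.frame(pairs), c("count", "percent"),
                         "calibration pairs")
  if (nrow(pairs) == 0) validation_error("at least one calibration pair needed")
  if (any(pairs$count <= 0) || any(pairs$percent <= 0))
    validation_error("calibration counts and percentages must be positive")
  if (is.na(count) || count < 0) validation_error("count must be >= 0")
  round(mean(pairs$percent * count / pairs$count), 2)
}
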