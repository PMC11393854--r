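#' Cohort container for CMMC monitoring data
#'
#' A `cmmc_cohort` bundles the three tables of a circulating multiple
#' myeloma cell (CMMC) monitoring study: one row per patient
#' (stage, staging systems, best response, survival), one row per CMMC
#' enumeration (absolute count per 4 mL of peripheral blood plus the
#' co-measured biochemical markers), and optionally one row per bone-marrow
#' MRD measurement. All downstream analyses take this container.
#'
#' @param patients data.frame with columns `patient_id`, `stage` (`"SMM"` or
#'   `"MM"`), `age_years`, `sex`, `iss`, `r_iss`, `best_response`
#'   (`CR`/`VGPR`/`PR`/`MR`/`SD`/`PD`), `pfs_months`, `pfs_event`,
#'   `os_months`, `os_event`. Only `patient_id` and `stage` are mandatory
#'   values; the rest may be `NA`.
#' @param timepoints data.frame with columns `patient_id`, `time_months`,
#'   `phase` (one of `diagnosis`, `untreated_followup`, `induction`,
#'   `consolidation`, `maintenance`, `progression`), `cmmc_count`
#'   (non-negative integer) and the biomarker columns `beta2m`, `albumin`,
#'   `calcium`, `crp`, `ldh`, `m_protein`, `kappa_lambda_ratio`,
#'   `total_protein`, `bm_pc_percent` (any of which may be `NA`).
#' @param mrd optional data.frame with columns `patient_id`, `timepoint`
#'   (`post_induction` or `pre_maintenance`), `mrd_value`, `detectable`,
#'   `hemodiluted`, `sensitivity`.
#' @return An object of class `cmmc_cohort`: a list with elements
#'   `patients`, `timepoints` and `mrd` (the latter possibly `NULL`),
#'   validated and sorted by `(patient_id, time_months)`.
#' @details Validation enforces: unique, non-missing `patient_id`; stages
#'   and phases drawn from their fixed vocabularies; integer CMMC counts
#'   `>= 0`; strictly increasing `time_months` within a patient (duplicated
#'   `(patient_id, time_months)` rows are rejected); `pfs_months <=
#'   os_months` where both are present; every timepoint/MRD `patient_id`
#'   present in `patients`; and `detectable` MRD values at or above the
#'   assay `sensitivity`.
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
cmmc_cohort <- function(patients, timepoints, mrd = NULL) {
  patients <- validate_patients(patients)
  timepoints <- validate_timepoints(timepoints, patients$patient_id)
  if (!is.null(mrd)) mrd <- validate_mrd(mrd, patients$patient_id)
  structure(list(patients = patients, timepoints = timepoints, mrd = mrd),
            class = "cmmc_cohort")
}

#' @export
print.cmmc_cohort <- function(x, ...) {
  cat("<cmmc_cohort>\n")
  cat("  patients:  ", nrow(x$patients),
      sprintf(" (SMM %d / MM %d)", sum(x$patients$stage == "SMM"),
              sum(x$patients$stage == "MM")), "\n", sep = "")
  cat("  timepoints:", nrow(x$timepoints), "\n")
  cat("  mrd:       ", if (is.null(x$mrd)) "none" else nrow(x$mrd), "\n")
  invisible(x)
}

PATIENT_COLS <- c("patient_id", "stage", "age_years", "sex", "iss", "r_iss",
                  "best_response", "pfs_months", "pfs_event", "os_months",
                  "os_event")
TIMEPOINT_COLS <- c("patient_id", "time_months", "phase", "cmmc_count",
                    "beta2m", "albumin", "calcium", "crp", "ldh", "m_protein",
                    "kappa_lambda_ratio", "total_protein", "bm_pc_percent")
MRD_COLS <- c("patient_id", "timepoint", "mrd_value", "detectable",
              "hemodiluted", "sensitivity")

PHASES <- c("diagnosis", "untreated_followup", "induction", "consolidation",
            "maintenance", "progression")
RESPONSES <- c("CR", "VGPR", "PR", "MR", "SD", "PD")
BIOMARKER_COLS <- c("beta2m", "albumin", "calcium", "crp", "ldh", "m_protein",
                    "kappa_lambda_ratio", "total_protein", "bm_pc_percent")

check_columns <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    format_error(sprintf("%s table is missing mandatory column(s): %s",
                         what, paste(miss, collapse = ", ")))
  df[required]
}

check_domain <- function(x, domain, what, allow_na = TRUE) {
  bad <- !(x %in% domain) & !(allow_na & is.na(x))
  if (any(bad))
    validation_error(sprintf(
      "invalid %s value(s) %s at row(s) %s (allowed: %s)",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(which(bad), collapse = ", "), paste(domain, collapse = ", ")))
  x
}

as_boolean <- function(x, what) {
  if (is.logical(x)) return(x)
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "True", "true", "1", 1)] <- TRUE
  out[x %in% c("FALSE", "False", "false", "0", 0)] <- FALSE
  unparsed <- is.na(out) & !is.na(x)
  if (any(unparsed))
    validation_error(sprintf("column %s: cannot interpret value(s) %s as boolean",
                             what, paste(unique(x[unparsed]), collapse = ", ")))
  out
}

validate_patients <- function(patients) {
  patients <- check_columns(as.data.frame(patients), PATIENT_COLS, "patients")
  if (nrow(patients) == 0) return(patients)
  if (anyNA(patients$patient_id) || any(patients$patient_id == ""))
    validation_error("patient_id must never be missing")
  if (anyDuplicated(patients$patient_id))
    validation_error(sprintf("duplicated patient_id: %s",
      paste(unique(patients$patient_id[duplicated(patients$patient_id)]),
            collapse = ", ")))
  check_domain(patients$stage, c("SMM", "MM"), "stage", allow_na = FALSE)
  check_domain(patients$sex, c("F", "M"), "sex")
  check_domain(patients$iss, c("I", "II", "III"), "iss")
  check_domain(patients$r_iss, c("I", "II", "III"), "r_iss")
  check_domain(patients$best_response, RESPONSES, "best_response")
  for (col in c("pfs_months", "os_months")) {
    v <- patients[[col]]
    if (any(!is.na(v) & v < 0))
      validation_error(sprintf("%s must be non-negative", col))
  }
  patients$pfs_event <- as_boolean(patients$pfs_event, "pfs_event")
  patients$os_event <- as_boolean(patients$os_event, "os_event")
  both <- !is.na(patients$pfs_months) & !is.na(patients$os_months)
  bad <- both & patients$pfs_months > patients$os_months
  if (any(bad))
    validation_error(sprintf("pfs_months > os_months for patient(s): %s",
                             paste(patients$patient_id[bad], collapse = ", ")))
  patients <- patients[order(patients$patient_id), , drop = FALSE]
  rownames(patients) <- NULL
  patients
}

validate_timepoints <- function(timepoints, patient_ids) {
  timepoints <- check_columns(as.data.frame(timepoints), TIMEPOINT_COLS,
                              "timepoints")
  if (nrow(timepoints) == 0) return(timepoints)
  orphan <- !(timepoints$patient_id %in% patient_ids)
  if (any(orphan))
    referential_error(sprintf(
      "timepoint patient_id(s) absent from patients table: %s",
      paste(unique(timepoints$patient_id[orphan]), collapse = ", ")))
  check_domain(timepoints$phase, PHASES, "phase", allow_na = FALSE)
  cnt <- timepoints$cmmc_count
  bad <- is.na(cnt) | cnt < 0 | (suppressWarnings(as.numeric(cnt)) %% 1 != 0)
  if (any(bad))
    validation_error(sprintf(
      "cmmc_count must be an integer >= 0; violated at row(s) %s (value(s) %s)",
      paste(which(bad), collapse = ", "),
      paste(cnt[bad], collapse = ", ")))
  timepoints$cmmc_count <- as.integer(cnt)
  if (any(is.na(timepoints$time_months) | timepoints$time_months < 0))
    validation_error("time_months must be a non-negative number")
  key <- paste(timepoints$patient_id, timepoints$time_months)
  if (anyDuplicated(key))
    validation_error(sprintf("duplicated (patient_id, time_months) at row(s) %s",
      paste(which(duplicated(key)), collapse = ", ")))
  ord <- order(timepoints$patient_id, timepoints$time_months)
  timepoints <- timepoints[ord, , drop = FALSE]
  rownames(timepoints) <- NULL
  timepoints
}

validate_mrd <- function(mrd, patient_ids) {
  mrd <- check_columns(as.data.frame(mrd), MRD_COLS, "mrd")
  if (nrow(mrd) == 0) return(mrd)
  orphan <- !(mrd$patient_id %in% patient_ids)
  if (any(orphan))
    referential_error(sprintf(
      "mrd patient_id(s) absent from patients table: %s",
      paste(unique(mrd$patient_id[orphan]), collapse = ", ")))
  check_domain(mrd$timepoint, c("post_induction", "pre_maintenance"),
               "mrd timepoint", allow_na = FALSE)
  mrd$detectable <- as_boolean(mrd$detectable, "detectable")
  mrd$hemodiluted <- as_boolean(mrd$hemodiluted, "hemodiluted")
  if (anyNA(mrd$detectable) || anyNA(mrd$hemodiluted))
    validation_error("detectable and hemodiluted flags must not be missing")
  mrd$sensitivity[is.na(mrd$sensitivity)] <- 1e-5
  if (any(!is.na(mrd$mrd_value) & mrd$mrd_value < 0))
    validation_error("mrd_value must be non-negative")
  bad <- mrd$detectable & (is.na(mrd$mrd_value) | mrd$mrd_value < mrd$sensitivity)
  if (any(bad))
    validation_error(sprintf(
      "detectable MRD with value below sensitivity at row(s) %s",
      paste(which(bad), collapse = ", ")))
  mrd <- mrd[order(mrd$patient_id, mrd$timepoint), , drop = FALSE]
  rownames(mrd) <- NULL
  mrd
}

empty_patients <- function() {
  data.frame(patient_id = character(), stage = character(),
             age_years = integer(), sex = character(), iss = character(),
             r_iss = character(), best_response = character(),
             pfs_months = numeric(), pfs_event = logical(),
             os_months = numeric(), os_event = logical(),
             stringsAsFactors = FALSE)
}

empty_timepoints <- function() {
  df <- data.frame(patient_id = character(), time_months = numeric(),
                   phase = character(), cmmc_count = integer(),
                   stringsAsFactors = FALSE)
  for (b in BIOMARKER_COLS) df[[b]] <- numeric()
  df
}

empty_mrd <- function() {
  data.frame(patient_id = character(), timepoint = character(),
             mrd_value = numeric(), detectable = logical(),
             hemodiluted = logical(), sensitivity = numeric(),
             stringsAsFactors = FALSE)
}
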