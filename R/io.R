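#' Read a CMMC monitoring cohort from CSV files
#'
#' Reads the patient, timepoint and (optionally) MRD tables from
#' comma-separated UTF-8 files with a header row naming exactly the schema
#' columns (see [cmmc_cohort()]). Empty cells denote missing values; no
#' sentinel strings or thousands separators are accepted.
#'
#' @param patients_path,timepoints_path,mrd_path Paths to the CSV files;
#'   `mrd_path` may be `NULL` when no MRD table exists.
#' @return A validated [cmmc_cohort()], rows sorted by
#'   `(patient_id, time_months)`.
#' @examples
#' dir <- tempfile(); coh <- generate_cohort(generator_config(5, seed = 1))$cohort
#' paths <- write_cohort(coh, dir)
#' coh2 <- read_cohort(paths["patients"], paths["timepoints"], paths["mrd"])
#' @export
read_cohort <- function(patients_path, timepoints_path, mrd_path = NULL) {
  patients <- read_cmmc_csv(patients_path, PATIENT_COLS, "patients")
  timepoints <- read_cmmc_csv(timepoints_path, TIMEPOINT_COLS, "timepoints")
  mrd <- if (!is.null(mrd_path)) read_cmmc_csv(mrd_path, MRD_COLS, "mrd")
  cmmc_cohort(patients, timepoints, mrd)
}

read_cmmc_csv <- function(path, required, what) {
  if (!file.exists(path))
    format_error(sprintf("%s file not found: %s", what, path))
  df <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                 check.names = FALSE, fileEncoding = "UTF-8")
  check_columns(df, required, what)
}

#' Write a cohort to CSV files
#'
#' Writes `patients.csv`, `timepoints.csv` and (when present) `mrd.csv`
#' into `directory`, creating it if needed. Missing values are written as
#' empty cells so that [read_cohort()] round-trips the cohort
#' field-for-field.
#'
#' @param cohort A [cmmc_cohort()].
#' @param directory Output directory.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "cmmc_cohort"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    cmmc_error(sprintf("cannot create directory %s", directory), "cmmcdyn_io_error")
  paths <- c(patients = file.path(directory, "patients.csv"),
             timepoints = file.path(directory, "timepoints.csv"))
  write.csv(cohort$patients, paths["patients"], row.names = FALSE, na = "")
  write.csv(cohort$timepoints, paths["timepoints"], row.names = FALSE, na = "")
  if (!is.null(cohort$mrd)) {
    paths["mrd"] <- file.path(directory, "mrd.csv")
    write.csv(cohort$mrd, paths["mrd"], row.names = FALSE, na = "")
  }
  invisible(paths)
}

CNA_STATES <- c("del", "neutral", "gain", "amp")
CHROMS <- c(as.character(1:22), "X", "Y")

#' Single-cell copy-number profiles
#'
#' Container for arm-level copy-number states of a set of single cells from
#' one patient. Arms not listed for a cell are implicitly `neutral`.
#'
#' @param states data.frame with columns `cell_id`, `patient_id`, `chrom`
#'   (1-22, X, Y), `arm` (`"p"`/`"q"`) and `state` (one of `del`, `neutral`,
#'   `gain`, `amp`).
#' @param ploidy data.frame with columns `cell_id`, `ploidy` (> 0), one row
#'   per cell; cells listed here but absent from `states` are all-neutral.
#' @return Object of class `cell_profiles`.
#' @export
cell_profiles <- function(states, ploidy) {
  states <- check_columns(as.data.frame(states),
                          c("cell_id", "patient_id", "chrom", "arm", "state"),
                          "cell states")
  ploidy <- check_columns(as.data.frame(ploidy), c("cell_id", "ploidy"),
                          "cell ploidy")
  states$chrom <- as.character(states$chrom)
  bad_state <- !(states$state %in% CNA_STATES)
  if (any(bad_state))
    format_error(sprintf("unknown copy-number state token(s): %s (allowed: %s)",
                         paste(unique(states$state[bad_state]), collapse = ", "),
                         paste(CNA_STATES, collapse = "/")))
  check_domain(states$chrom, CHROMS, "chrom", allow_na = FALSE)
  check_domain(states$arm, c("p", "q"), "arm", allow_na = FALSE)
  key <- paste(states$cell_id, states$chrom, states$arm)
  if (anyDuplicated(key))
    validation_error(sprintf("duplicate (cell, chrom, arm) state at row(s) %s",
                             paste(which(duplicated(key)), collapse = ", ")))
  if (nrow(states) && !all(states$cell_id %in% ploidy$cell_id))
    validation_error("every cell in the state table needs a ploidy entry")
  if (any(!is.na(ploidy$ploidy) & ploidy$ploidy <= 0))
    validation_error("ploidy must be positive")
  if (anyDuplicated(ploidy$cell_id))
    validation_error("duplicated cell_id in ploidy table")
  structure(list(states = states, ploidy = ploidy), class = "cell_profiles")
}

#' @export
print.cell_profiles <- function(x, ...) {
  cat("<cell_profiles> ", nrow(x$ploidy), " cells, ",
      nrow(x$states), " explicit arm states\n", sep = "")
  invisible(x)
}

#' Bulk diagnostic copy-number profile
#'
#' Arm-level copy-number states of the diagnostic bulk (CD138+ bone-marrow)
#' sample, with its estimated tumor fraction and ploidy.
#'
#' @param patient_id Patient identifier.
#' @param states data.frame with columns `chrom`, `arm`, `state`.
#' @param tumor_fraction Fraction of tumor DNA in the sample, in \[0, 1\].
#' @param ploidy Positive real.
#' @return Object of class `bulk_profile`.
#' @export
bulk_profile <- function(patient_id, states, tumor_fraction, ploidy) {
  states <- check_columns(as.data.frame(states), c("chrom", "arm", "state"),
                          "bulk states")
  states$chrom <- as.character(states$chrom)
  bad_state <- !(states$state %in% CNA_STATES)
  if (any(bad_state))
    format_error(sprintf("unknown copy-number state token(s): %s",
                         paste(unique(states$state[bad_state]), collapse = ", ")))
  if (anyDuplicated(paste(states$chrom, states$arm)))
    validation_error("duplicate (chrom, arm) in bulk profile")
  if (is.na(tumor_fraction) || tumor_fraction < 0 || tumor_fraction > 1)
    validation_error("tumor_fraction must lie in [0, 1]")
  if (is.na(ploidy) || ploidy <= 0) validation_error("ploidy must be positive")
  structure(list(patient_id = patient_id, states = states,
                 tumor_fraction = tumor_fraction, ploidy = ploidy),
            class = "bulk_profile")
}

#' Read single-cell and bulk copy-number tables
#'
#' @param cells_path CSV with columns `cell_id`, `patient_id`, `chrom`,
#'   `arm`, `state`, `ploidy` (per-cell ploidy, repeated across a cell's
#'   rows).
#' @param bulk_path CSV with columns `patient_id`, `chrom`, `arm`, `state`,
#'   `tumor_fraction`, `ploidy`.
#' @return list with elements `cells` ([cell_profiles()]) and `bulk`
#'   ([bulk_profile()]).
#' @export
read_cna_tables <- function(cells_path, bulk_path) {
  cells <- read_cmmc_csv(cells_path,
                         c("cell_id", "patient_id", "chrom", "arm", "state",
                           "ploidy"), "cell CNA")
  ploidy <- unique(cells[c("cell_id", "ploidy")])
  if (anyDuplicated(ploidy$cell_id))
    validation_error("inconsistent ploidy values within a cell")
  prof <- cell_profiles(cells[c("cell_id", "patient_id", "chrom", "arm", "state")],
                        ploidy)
  bulk <- read_cmmc_csv(bulk_path,
                        c("patient_id", "chrom", "arm", "state",
                          "tumor_fraction", "ploidy"), "bulk CNA")
  if (length(unique(bulk$patient_id)) != 1)
    validation_error("bulk CNA table must describe a single patient")
  bp <- bulk_profile(bulk$patient_id[1], bulk[c("chrom", "arm", "state")],
                     unique(bulk$tumor_fraction)[1], unique(bulk$ploidy)[1])
  list(cells = prof, bulk = bp)
}
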