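#' Bundled example data
#'
#' Small plain-text datasets shipped with the package, encoding published
#' desk-scale inputs of a CMMC monitoring study:
#'
#' * `example_smm_cohort()` — the serial CMMC enumerations of seven
#'   untreated smouldering-myeloma patients (20 timepoints). Four of the
#'   seven later progressed to MM; their post-progression enumerations
#'   carry phase `progression`. Post-progression rows are printed on a
#'   post-progression clock in the source table; the bundled encoding
#'   shifts them after the last untreated timepoint so that time is
#'   strictly increasing, since analysis windows are driven by the phase
#'   column, not the clock.
#' * `example_flow_calibration()` — three (absolute count, flow-cytometry
#'   percentage) calibration pairs measured on the same diagnostic
#'   samples, used by [flow_equivalent_percentage()].
#' * `example_single_cell_yields()` — per-patient cell accounting of a
#'   four-patient single-cell workup (cells enumerated, redetected,
#'   QC-passing, aberrant), used by [single_cell_yield_rates()].
#'
#' @return `example_smm_cohort()` a [cmmc_cohort()]; the others a
#'   data.frame.
#' @examples
#' stratify_by_baseline_median(baseline_counts(example_smm_cohort()))
#' @export
example_smm_cohort <- function() {
  read_cohort(
    system.file("extdata", "smm_patients.csv", package = "cmmcdyn",
                mustWork = TRUE),
    system.file("extdata", "smm_timepoints.csv", package = "cmmcdyn",
                mustWork = TRUE))
}

#' @rdname example_smm_cohort
#' @export
example_flow_calibration <- function() {
  read.csv(system.file("extdata", "flow_calibration.csv", package = "cmmcdyn",
                       mustWork = TRUE))
}

#' @rdname example_smm_cohort
#' @export
example_single_cell_yields <- function() {
  read.csv(system.file("extdata", "single_cell_yields.csv",
                       package = "cmmcdyn", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
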