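# Arm-level clonality analysis of single-cell copy-number profiles.
# States gain and amp are distinct in the input but collapse to one
# direction ("gain") for alteration identity; del maps to "loss".

state_direction <- function(state) {
  c(del = "loss", gain = "gain", amp = "gain", neutral = NA_character_)[state]
}

#' Call arm-level alterations across single cells
#'
#' Produces one call per (chrom, arm, direction) seen in at least one
#' cell, with the number of carrying cells and the fraction of the total.
#' `gain` and `amp` states collapse to direction `gain`; `del` maps to
#' `loss`; `neutral` (explicit or implicit) contributes nothing.
#'
#' @param cells A [cell_profiles()] object; all cells must belong to one
#'   patient.
#' @return data.frame of class `alteration_calls` with columns `chrom`,
#'   `arm`, `direction`, `n_cells`, `n_total`, `fraction`; the patient id
#'   is attached as `attr(, "patient_id")`.
#' @export
call_alterations <- function(cells) {
  stopifnot(inherits(cells, "cell_profiles"))
  if (nrow(cells$ploidy) == 0) validation_error("need >= 1 cell")
  pid <- unique(cells$states$patient_id)
  if (length(pid) > 1)
    validation_error("cells from multiple patients; call one patient at a time")
  if (length(pid) == 0) pid <- NA_character_
  n_total <- nrow(cells$ploidy)
  st <- cells$states
  st$direction <- state_direction(st$state)
  st <- st[!is.na(st$direction), , drop = FALSE]
  if (nrow(st) == 0) {
    out <- data.frame(chrom = character(), arm = character(),
                      direction = character(), n_cells = integer(),
                      n_total = integer(), fraction = numeric())
  } else {
    agg <- stats::aggregate(cell_id ~ chrom + arm + direction, data = st,
                            FUN = function(v) length(unique(v)))
    out <- data.frame(chrom = agg$chrom, arm = agg$arm,
                      direction = agg$direction, n_cells = agg$cell_id,
                      n_total = n_total, fraction = agg$cell_id / n_total,
                      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$arm, out$direction), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "patient_id") <- pid
  class(out) <- c("alteration_calls", class(out))
  out
}

#' Classify alteration clonality
#'
#' Assigns each call exactly one category, generalizing cell-count rules
#' stated for a 19-cell experiment to arbitrary n: `rare` when carried by
#' at most two cells or by a fraction <= 0.11 (this rule takes precedence),
#' `clonal` when the fraction is >= 0.89, `subclonal` otherwise.
#'
#' @param calls Output of [call_alterations()].
#' @param n_total Total number of cells (defaults to the calls' own
#'   `n_total`).
#' @return `calls` with a `category` column added.
#' @export
classify_clonality <- function(calls, n_total = NULL) {
  calls <- as.data.frame(calls)
  if (!is.null(n_total)) {
    if (n_total < 1) validation_error("n_total must be >= 1")
    calls$n_total <- n_total
    calls$fraction <- calls$n_cells / n_total
  }
  cat_of <- function(n, f) {
    if (n <= 2 || f <= 0.11) "rare" else if (f >= 0.89) "clonal" else "subclonal"
  }
  calls$category <- mapply(cat_of, calls$n_cells, calls$fraction)
  class(calls) <- unique(c("alteration_calls", class(calls)))
  calls
}

bulk_alteration_set <- function(bulk) {
  st <- bulk$states
  st$direction <- state_direction(st$state)
  st <- st[!is.na(st$direction), , drop = FALSE]
  paste(st$chrom, st$arm, st$direction)
}

#' Flag alterations absent from the diagnostic bulk profile
#'
#' An alteration is `emerging` when its (chrom, arm, direction) is absent
#' from the bulk profile — the arm is neutral there or altered in the
#' opposite direction (a cell-level deletion over a bulk gain is still
#' emerging: summed sub-clonal events can cancel into a "mixed" bulk
#' signal).
#'
#' @param calls Output of [call_alterations()] (optionally classified).
#' @param bulk A [bulk_profile()] of the same patient.
#' @return `calls` with an `emerging` logical column added.
#' @export
detect_emerging <- function(calls, bulk) {
  stopifnot(inherits(bulk, "bulk_profile"))
  pid <- attr(calls, "patient_id")
  if (!is.na(pid) && !identical(pid, bulk$patient_id))
    validation_error(sprintf("patient mismatch: cells %s vs bulk %s",
                             pid, bulk$patient_id))
  bulk_set <- bulk_alteration_set(bulk)
  calls <- as.data.frame(calls)
  calls$emerging <- !(paste(calls$chrom, calls$arm, calls$direction) %in% bulk_set)
  attr(calls, "patient_id") <- pid
  class(calls) <- unique(c("alteration_calls", class(calls)))
  calls
}

#' Overlap between cell-level and bulk alteration sets
#'
#' The cell-side set keeps majority calls (fraction >= 0.5), since the
#' bulk profile reflects dominant clones; overlap is summarized by the
#' Jaccard index over (chrom, arm, direction) identities.
#'
#' @inheritParams detect_emerging
#' @return list with `shared`, `cell_only`, `bulk_only` (character vectors
#'   of "chrom arm direction") and `jaccard` (1 when both sets are empty).
#' @export
compare_bulk_cells <- function(calls, bulk) {
  stopifnot(inherits(bulk, "bulk_profile"))
  calls <- as.data.frame(calls)
  cell_set <- paste(calls$chrom, calls$arm, calls$direction)[calls$fraction >= 0.5]
  bulk_set <- bulk_alteration_set(bulk)
  u <- union(cell_set, bulk_set)
  list(shared = sort(intersect(cell_set, bulk_set)),
       cell_only = sort(setdiff(cell_set, bulk_set)),
       bulk_only = sort(setdiff(bulk_set, cell_set)),
       jaccard = if (length(u) == 0) 1 else
         length(intersect(cell_set, bulk_set)) / length(u))
}

#' Main ploidy of a single-cell experiment
#'
#' Per-cell ploidies are rounded to the nearest integer (half away from
#' zero) and the mode is reported; a tie between modes is broken toward
#' the lower ploidy and flagged.
#'
#' @param cells A [cell_profiles()] object.
#' @return list with `main_ploidy`, `distribution` (table of rounded
#'   ploidies) and `tie` flag.
#' @export
ploidy_summary <- function(cells) {
  stopifnot(inherits(cells, "cell_profiles"))
  pl <- cells$ploidy$ploidy
  if (!length(pl)) validation_error("need >= 1 cell")
  rounded <- round_half_up(pl)
  tab <- table(rounded)
  top <- as.integer(names(tab)[tab == max(tab)])
  list(main_ploidy = min(top), distribution = tab, tie = length(top) > 1)
}

#' Recovery and quality yields of single-cell CMMC workups
#'
#' Aggregates per-patient cell accounting of a single-cell sorting and
#' sequencing workflow — cells enumerated in blood, cells redetected and
#' sorted as singles, cells passing amplification/sequencing QC, and
#' cells with an aberrant copy-number profile — into pooled percentage
#' yields.
#'
#' @param yields data.frame with columns `patient_id`, `enumerated`,
#'   `recovered`, `qc_passed`, `aberrant`.
#' @return list with `redetection_pct` (recovered/enumerated),
#'   `qc_pct` (qc_passed/recovered), `aberrant_pct` (aberrant/qc_passed),
#'   each pooled over patients, plus the pooled `totals`.
#' @examples
#' single_cell_yield_rates(example_single_cell_yields())
#' @export
single_cell_yield_rates <- function(yields) {
  yields <- check_columns(as.data.frame(yields),
                          c("patient_id", "enumerated", "recovered",
                            "qc_passed", "aberrant"), "single-cell yields")
  if (nrow(yields) == 0) validation_error("empty yield table")
  bad <- with(yields, recovered > enumerated | qc_passed > recovered |
                aberrant > qc_passed)
  if (any(bad))
    validation_error("yields must be non-increasing along the workflow")
  tot <- colSums(yields[c("enumerated", "recovered", "qc_passed", "aberrant")])
  list(redetection_pct = 100 * tot[["recovered"]] / tot[["enumerated"]],
       qc_pct = 100 * tot[["qc_passed"]] / tot[["recovered"]],
       aberrant_pct = 100 * tot[["aberrant"]] / tot[["qc_passed"]],
       totals = tot)
}
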