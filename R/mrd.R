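MRD_PHASE_WINDOW <- c(post_induction = "induction",
                      pre_maintenance = "consolidation")

#' Pair bone-marrow MRD measurements with contemporaneous CMMC enumerations
#'
#' Each MRD record pairs with the enumeration of the same patient taken in
#' the phase window matching its milestone label: `post_induction` pairs
#' with the last induction enumeration, `pre_maintenance` with the last
#' consolidation enumeration. MRD records that are both hemodiluted and
#' undetectable are retained but flagged `excluded_hemodilution` (their
#' undetectable result may be a false negative) and are omitted from
#' concordance summaries. MRD records with no matching enumeration go to a
#' remainder report attached as `attr(, "unpaired")`.
#'
#' @param cohort A [cmmc_cohort()] with a non-`NULL` MRD table.
#' @param window_months Optional numeric fallback: when a patient has no
#'   enumeration in the matching phase, pair with the enumeration closest
#'   to the cohort-median time of that phase, provided it lies within
#'   `window_months` of it. `NULL` (default) disables the fallback.
#' @return data.frame of class `cmmc_pairs` with columns `patient_id`,
#'   `timepoint`, `mrd_detectable`, `mrd_value`, `cmmc_count`,
#'   `cmmc_detectable` (count >= 1) and `excluded_hemodilution`; unpaired
#'   MRD records in `attr(, "unpaired")`. Every MRD record is exactly one
#'   of paired, excluded-but-paired, or unpaired.
#' @export
pair_measurements <- function(cohort, window_months = NULL) {
  stopifnot(inherits(cohort, "cmmc_cohort"))
  if (is.null(cohort$mrd) || nrow(cohort$mrd) == 0)
    validation_error("cohort carries no MRD records to pair")
  mrd <- cohort$mrd
  tp <- cohort$timepoints
  phase_med <- tapply(tp$time_months, tp$phase, median)
  rows <- vector("list", nrow(mrd))
  unpaired <- logical(nrow(mrd))
  for (i in seq_len(nrow(mrd))) {
    m <- mrd[i, ]
    want_phase <- MRD_PHASE_WINDOW[[m$timepoint]]
    cand <- tp[tp$patient_id == m$patient_id & tp$phase == want_phase, ,
               drop = FALSE]
    if (nrow(cand) == 0 && !is.null(window_months) &&
        !is.na(phase_med[want_phase])) {
      anchor <- phase_med[[want_phase]]
      cand <- tp[tp$patient_id == m$patient_id &
                   abs(tp$time_months - anchor) <= window_months, ,
                 drop = FALSE]
      cand <- cand[order(abs(cand$time_months - anchor)), , drop = FALSE]
      cand <- head(cand, 1)
    }
    if (nrow(cand) == 0) { unpaired[i] <- TRUE; next }
    enum <- cand[which.max(cand$time_months), ]
    rows[[i]] <- data.frame(
      patient_id = m$patient_id, timepoint = m$timepoint,
      mrd_detectable = m$detectable, mrd_value = m$mrd_value,
      cmmc_count = enum$cmmc_count,
      cmmc_detectable = enum$cmmc_count >= 1,
      excluded_hemodilution = m$hemodiluted & !m$detectable,
      stringsAsFactors = FALSE)
  }
  kept <- rows[!unpaired]
  pairs <- if (length(kept))
    do.call(rbind, c(kept, list(make.row.names = FALSE)))
  else
    data.frame(patient_id = character(), timepoint = character(),
                        mrd_detectable = logical(), mrd_value = numeric(),
                        cmmc_count = integer(), cmmc_detectable = logical(),
                        excluded_hemodilution = logical())
  attr(pairs, "unpaired") <- mrd[unpaired, , drop = FALSE]
  class(pairs) <- c("cmmc_pairs", class(pairs))
  pairs
}

#' Concordance between MRD and CMMC detectability
#'
#' A pair is concordant when bone-marrow MRD and peripheral-blood CMMCs
#' agree on detectability: both detectable or both undetectable.
#' Hemodilution-excluded pairs do not enter the summary.
#'
#' @param pairs Output of [pair_measurements()] (or any data.frame with
#'   columns `mrd_detectable`, `cmmc_detectable`, `excluded_hemodilution`).
#' @return list of class `concordance_summary`: `n_pairs`, `n_concordant`,
#'   `fraction_concordant`, `n_excluded` and the 2x2 `table`
#'   (MRD +/- by CMMC +/-).
#' @export
concordance <- function(pairs) {
  pairs <- as.data.frame(pairs)
  usable <- pairs[!pairs$excluded_hemodilution, , drop = FALSE]
  if (nrow(usable) == 0)
    validation_error("no usable (non-excluded) pairs")
  tab <- table(factor(ifelse(usable$mrd_detectable, "mrd+", "mrd-"),
                      levels = c("mrd+", "mrd-")),
               factor(ifelse(usable$cmmc_detectable, "cmmc+", "cmmc-"),
                      levels = c("cmmc+", "cmmc-")))
  n_conc <- tab["mrd+", "cmmc+"] + tab["mrd-", "cmmc-"]
  structure(list(n_pairs = nrow(usable), n_concordant = unname(n_conc),
                 fraction_concordant = unname(n_conc) / nrow(usable),
                 n_excluded = sum(pairs$excluded_hemodilution),
                 table = tab),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("MRD-CMMC concordance: %d/%d pairs (%.0f%%), %d excluded for hemodilution\n",
              x$n_concordant, x$n_pairs, 100 * x$fraction_concordant,
              x$n_excluded))
  print(x$table)
  invisible(x)
}

#' Cross-tabulate coMMstant index against per-patient MRD positivity
#'
#' A patient counts as MRD-positive when any of their non-excluded paired
#' MRD measurements is detectable. Patients with an indeterminate
#' coMMstant index or no usable pair are dropped. The association is
#' tested with [fisher_exact_2x2()]; a degenerate margin (e.g. every
#' patient MRD-negative) is flagged instead of tested.
#'
#' @param commstant data.frame from [classify_cohort_commstant()].
#' @param pairs Output of [pair_measurements()].
#' @return list: `table` (index 1/0 x MRD +/-), `fraction_positive` per
#'   index group, `fisher` (or `NULL`), `degenerate` flag.
#' @export
crosstab_commstant_mrd <- function(commstant, pairs) {
  pairs <- as.data.frame(pairs)
  usable <- pairs[!pairs$excluded_hemodilution, , drop = FALSE]
  pos <- tapply(usable$mrd_detectable, usable$patient_id, any)
  cls <- commstant[commstant$index %in% c("1", "0"), , drop = FALSE]
  common <- intersect(cls$patient_id, names(pos))
  if (!length(common))
    validation_error("no patients with both a coMMstant index and a usable MRD pair")
  idx <- factor(cls$index[match(common, cls$patient_id)], levels = c("1", "0"))
  mp <- factor(ifelse(pos[common], "mrd+", "mrd-"), levels = c("mrd+", "mrd-"))
  tab <- table(coMMstant = idx, mrd = mp)
  degenerate <- any(rowSums(tab) < 1) || any(colSums(tab) < 1)
  fisher <- if (!degenerate) fisher_exact_2x2(tab) else NULL
  frac <- tab[, "mrd+"] / pmax(rowSums(tab), 1)
  list(table = tab, fraction_positive = frac, fisher = fisher,
       degenerate = degenerate)
}
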