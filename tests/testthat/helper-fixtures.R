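# In-code fixtures and independent oracles shared across the suite.

minimal_patients <- function(ids = "P1", stage = "MM") {
  n <- length(ids)
  data.frame(patient_id = ids, stage = rep_len(stage, n),
             age_years = NA_integer_, sex = NA_character_,
             iss = NA_character_, r_iss = NA_character_,
             best_response = NA_character_,
             pfs_months = 12, pfs_event = FALSE,
             os_months = 12, os_event = FALSE,
             stringsAsFactors = FALSE)
}

minimal_timepoints <- function(ids, times, phases, counts) {
  df <- data.frame(patient_id = ids, time_months = times, phase = phases,
                   cmmc_count = counts, stringsAsFactors = FALSE)
  for (b in c("beta2m", "albumin", "calcium", "crp", "ldh", "m_protein",
              "kappa_lambda_ratio", "total_protein", "bm_pc_percent"))
    df[[b]] <- NA_real_
  df
}

minimal_mrd <- function(ids, timepoint = "post_induction", value = 0.001,
                        detectable = TRUE, hemodiluted = FALSE) {
  data.frame(patient_id = ids, timepoint = timepoint, mrd_value = value,
             detectable = detectable, hemodiluted = hemodiluted,
             sensitivity = 1e-5, stringsAsFactors = FALSE)
}

write_cohort_csvs <- function(patients, timepoints, mrd = NULL,
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  pp <- file.path(dir, "patients.csv")
  tp <- file.path(dir, "timepoints.csv")
  utils::write.csv(patients, pp, row.names = FALSE, na = "")
  utils::write.csv(timepoints, tp, row.names = FALSE, na = "")
  mp <- NULL
  if (!is.null(mrd)) {
    mp <- file.path(dir, "mrd.csv")
    utils::write.csv(mrd, mp, row.names = FALSE, na = "")
  }
  list(patients = pp, timepoints = tp, mrd = mp)
}

# independent two-sided Fisher oracle: explicit hypergeometric enumeration
fisher_p_enumerated <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  sum(pr[pr <= pr[x == a] * (1 + 1e-7)])
}

# empirical survivor function (no censoring): S(t) = mean(T > t)
empirical_survival <- function(times, at) {
  vapply(at, function(t) mean(times > t), numeric(1))
}

make_cells <- function(states, ploidy) cell_profiles(states, ploidy)
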