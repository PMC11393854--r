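#' Configuration of the synthetic CMMC cohort generator
#'
#' Bundles and validates every ground-truth parameter of the generative
#' model: cohort composition, the zero-inflated negative-binomial count
#' model, the multiplicative beta2-microglobulin effect, the
#' proportional-hazards survival contrast between trajectory classes, the
#' MRD detectability coupling and the master seed.
#'
#' @param n_patients Number of patients (0 gives an empty cohort).
#' @param frac_mm Fraction of MM (vs SMM) patients; default 44/51.
#' @param frac_persistent Fraction of MM patients in the persistent
#'   (coMMstant = 1) trajectory class; default 0.375.
#' @param n_timepoints Enumerations per patient (>= 2), spaced
#'   `timepoint_spacing_months` apart; default 4 at 3-month spacing.
#' @param timepoint_spacing_months Months between enumerations.
#' @param count_dispersion Negative-binomial size parameter (> 0).
#' @param baseline_log_mean Log mean count at diagnosis for a patient at
#'   the beta2M reference value; default `log(350)`.
#' @param beta2m_effect Multiplicative change in expected CMMC count per
#'   mg/L of beta2-microglobulin; default 5.5.
#' @param beta2m_ref Reference beta2M anchoring `baseline_log_mean`
#'   (mg/L); default 3.5, the ISS stage boundary.
#' @param treatment_log_reduction Log change in expected count per
#'   treatment phase step (<= 0); default -1.5.
#' @param clearance_prob Probability that a clearing-class patient's
#'   post-baseline enumeration is a structural zero; default 0.9.
#' @param random_intercept_sd SD of the per-patient log-scale intercept.
#' @param hr_pfs,hr_os Hazard ratios (persistent vs clearing class) for
#'   progression-free and overall survival; defaults 4.554 and 7.805.
#' @param baseline_hazard_pfs,baseline_hazard_os Clearing-class
#'   exponential hazards (events/month); defaults give roughly 80%
#'   18-month PFS and 95% 18-month OS in that class.
#' @param censor_horizon_months Administrative censoring time; default 18.
#' @param mrd_sensitivity Assay sensitivity (fraction); default 1e-5.
#' @param missing_rate Probability that a biomarker cell is missing.
#' @param seed Master integer seed; identical configs (including seed)
#'   yield bit-identical cohorts.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients,
                             frac_mm = 44 / 51,
                             frac_persistent = 0.375,
                             n_timepoints = 4,
                             timepoint_spacing_months = 3,
                             count_dispersion = 2,
                             baseline_log_mean = log(350),
                             beta2m_effect = 5.5,
                             beta2m_ref = 3.5,
                             treatment_log_reduction = -1.5,
                             clearance_prob = 0.9,
                             random_intercept_sd = 0.5,
                             hr_pfs = 4.554,
                             hr_os = 7.805,
                             baseline_hazard_pfs = 0.0124,
                             baseline_hazard_os = 0.00285,
                             censor_horizon_months = 18,
                             mrd_sensitivity = 1e-5,
                             missing_rate = 0.05,
                             seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("frac_mm", "frac_persistent", "clearance_prob", "missing_rate",
              "mrd_sensitivity"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      config_error(sprintf("%s must lie in [0, 1]", f))
  for (f in c("count_dispersion", "hr_pfs", "hr_os", "baseline_hazard_pfs",
              "baseline_hazard_os", "beta2m_effect", "random_intercept_sd",
              "censor_horizon_months"))
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0)
      config_error(sprintf("%s must be positive", f))
  if (n_patients < 0 || n_patients %% 1 != 0)
    config_error("n_patients must be a non-negative integer")
  if (n_timepoints < 2 || n_timepoints %% 1 != 0)
    config_error("n_timepoints must be an integer >= 2")
  if (treatment_log_reduction > 0)
    config_error("treatment_log_reduction must be <= 0")
  structure(cfg, class = "generator_config")
}

# zero-truncated negative binomial via inverse CDF
rztnbinom <- function(n, mu, size) {
  p0 <- pnbinom(0, mu = mu, size = size)
  u <- runif(n, min = p0, max = 1)
  qnbinom(pmin(u, 1 - 1e-12), mu = mu, size = size)
}

response_thresholds <- function() {
  # cumulative thresholds on the latent logistic scale, anchored so the
  # clearing class reaches >=CR 60% and >=VGPR 76%
  c(CR = qlogis(0.60), VGPR = qlogis(0.76), PR = qlogis(0.91),
    MR = qlogis(0.95), SD = qlogis(0.99))
}

#' Generate a synthetic CMMC monitoring cohort with ground truth
#'
#' Simulates a cohort with the statistical structure the downstream
#' analyses assume. Counts follow a zero-inflated negative binomial whose
#' log mean is `baseline_log_mean + log(beta2m_effect) * (beta2m -
#' beta2m_ref) + treatment_log_reduction * phase_index + u_i`, with a
#' per-patient Gaussian random intercept `u_i`. Clearing-class patients
#' draw structural zeros with probability `clearance_prob` at
#' post-baseline phases; persistent-class patients draw zero-truncated
#' counts there, realizing "consistently detectable" by construction.
#' Beta2M declines under therapy (faster for the clearing class); the
#' other biomarkers load on a latent per-patient severity with the sign
#' pattern positive for beta2M, CRP, M-protein, negative for albumin.
#' PFS and OS are exponential proportional hazards with log-hazard offset
#' `log(hr)` for the persistent class, administratively censored at the
#' horizon; OS is generated first and progression added on top, so
#' `pfs_months <= os_months` holds and both marginal hazards match their
#' targets exactly. MRD detectability increases with the concurrent true
#' count; best response is drawn from a proportional-odds model with a
#' class offset.
#'
#' @param config A [generator_config()].
#' @return list with `cohort` (a [cmmc_cohort()]) and `truth` (list:
#'   per-patient `patients` data.frame with `latent_class`, `severity`,
#'   `random_intercept` and true hazards; per-observation `observations`
#'   data.frame with the true `log_mu` and the `structural_zero` flag).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  if (cfg$n_patients == 0) {
    cohort <- cmmc_cohort(empty_patients(), empty_timepoints(), empty_mrd())
    return(list(cohort = cohort,
                truth = list(patients = data.frame(), observations = data.frame())))
  }
  seeds <- substream_seeds(cfg$seed, 5)
  n <- cfg$n_patients
  ids <- sprintf("SIM_%04d", seq_len(n))

  ## stage, latent class, severity, random intercept
  set.seed(seeds[1])
  stage <- ifelse(runif(n) < cfg$frac_mm, "MM", "SMM")
  persistent <- stage == "MM" & runif(n) < cfg$frac_persistent
  severity <- rnorm(n) + 0.6 * persistent - 0.3 * (stage == "SMM")
  u <- rnorm(n, sd = cfg$random_intercept_sd)
  beta2m0 <- exp(log(3.2) + 0.35 * severity + rnorm(n, sd = 0.15))

  ## longitudinal counts and biomarkers
  set.seed(seeds[2])
  J <- cfg$n_timepoints
  obs <- expand.grid(j = seq_len(J) - 1L, i = seq_len(n))[, c("i", "j")]
  i <- obs$i; j <- obs$j
  mm <- stage[i] == "MM"
  phase <- ifelse(mm,
                  c("diagnosis", "induction", "consolidation",
                    "maintenance")[pmin(j, 3L) + 1L],
                  ifelse(j == 0, "diagnosis", "untreated_followup"))
  pidx <- ifelse(mm, pmin(j, 3L), 0L)
  decline <- ifelse(persistent[i], 0.05, 0.15) * mm
  beta2m <- beta2m0[i] * exp(-decline * pidx + rnorm(nrow(obs), sd = 0.05))
  log_mu <- cfg$baseline_log_mean +
    log(cfg$beta2m_effect) * (beta2m - cfg$beta2m_ref) +
    cfg$treatment_log_reduction * pidx + u[i]
  mu <- pmin(exp(log_mu), 1e7)
  post <- pidx >= 1
  structural <- !persistent[i] & post & runif(nrow(obs)) < cfg$clearance_prob
  count <- integer(nrow(obs))
  trunc_rows <- persistent[i] & post
  plain_rows <- !structural & !trunc_rows
  count[plain_rows] <- rnbinom(sum(plain_rows), mu = mu[plain_rows],
                               size = cfg$count_dispersion)
  count[trunc_rows] <- rztnbinom(sum(trunc_rows), mu = mu[trunc_rows],
                                 size = cfg$count_dispersion)

  sev <- severity[i]
  resp_shift <- ifelse(persistent[i], 0.15, 0.5) * pidx  # markers normalize under therapy
  albumin <- 4.1 - 0.4 * (sev - resp_shift) + rnorm(nrow(obs), sd = 0.25)
  calcium <- 9.4 + 0.5 * (sev - 0.5 * resp_shift) + rnorm(nrow(obs), sd = 0.4)
  crp <- exp(log(2.5) + 0.5 * (sev - resp_shift) + rnorm(nrow(obs), sd = 0.5))
  ldh <- 170 * exp(0.12 * (sev - 0.5 * resp_shift) + rnorm(nrow(obs), sd = 0.15))
  m_protein <- pmax(2.2 + 1.1 * sev + rnorm(nrow(obs), sd = 0.5), 0.05) *
    exp(-0.4 * resp_shift)
  klr <- exp(1.5 + 0.6 * (sev - resp_shift) + rnorm(nrow(obs), sd = 0.8))
  total_protein <- 6.3 + 0.5 * m_protein + rnorm(nrow(obs), sd = 0.3)
  bm_pc <- 100 * plogis(-2 + 0.8 * (sev - resp_shift) + rnorm(nrow(obs), sd = 0.5))

  timepoints <- data.frame(
    patient_id = ids[i],
    time_months = j * cfg$timepoint_spacing_months,
    phase = phase, cmmc_count = as.integer(count),
    beta2m = beta2m, albumin = albumin, calcium = calcium, crp = crp,
    ldh = ldh, m_protein = m_protein, kappa_lambda_ratio = klr,
    total_protein = total_protein, bm_pc_percent = bm_pc,
    stringsAsFactors = FALSE)
  if (cfg$missing_rate > 0)
    for (b in BIOMARKER_COLS)
      timepoints[[b]][runif(nrow(timepoints)) < cfg$missing_rate] <- NA_real_

  ## survival: death hazard first, progression added on top
  set.seed(seeds[3])
  h_os <- cfg$baseline_hazard_os * ifelse(persistent, cfg$hr_os, 1)
  h_pfs <- cfg$baseline_hazard_pfs * ifelse(persistent, cfg$hr_pfs, 1)
  h_prog <- pmax(h_pfs - h_os, 1e-10)
  t_death <- rexp(n, rate = h_os)
  t_prog <- rexp(n, rate = h_prog)
  horizon <- cfg$censor_horizon_months
  pfs_raw <- pmin(t_prog, t_death)
  pfs_months <- pmin(pfs_raw, horizon)
  pfs_event <- pfs_raw < horizon
  os_months <- pmin(t_death, horizon)
  os_event <- t_death < horizon

  ## best response (MM only): proportional odds with class offset
  set.seed(seeds[4])
  th <- response_thresholds()
  lat <- 1.9 * persistent - 0.15 * (severity - 0.6 * persistent) + rlogis(n)
  response <- ifelse(lat < th["CR"], "CR",
              ifelse(lat < th["VGPR"], "VGPR",
              ifelse(lat < th["PR"], "PR",
              ifelse(lat < th["MR"], "MR",
              ifelse(lat < th["SD"], "SD", "PD")))))
  response[stage == "SMM"] <- NA_character_

  iss <- cut(beta2m0, c(-Inf, 3.5, 5.5, Inf), labels = c("I", "II", "III"))
  patients <- data.frame(
    patient_id = ids, stage = stage,
    age_years = as.integer(round_half_up(61 + rnorm(n, sd = 7))),
    sex = ifelse(runif(n) < 0.59, "M", "F"),
    iss = as.character(iss), r_iss = as.character(iss),
    best_response = response,
    pfs_months = pfs_months, pfs_event = pfs_event,
    os_months = os_months, os_event = os_event,
    stringsAsFactors = FALSE)

  ## MRD records, detectability coupled to the concurrent true count
  set.seed(seeds[5])
  mrd <- generate_mrd(ids, stage, timepoints, cfg)

  cohort <- cmmc_cohort(patients, timepoints, mrd)
  truth <- list(
    patients = data.frame(patient_id = ids, stage = stage,
                          latent_class = ifelse(stage == "SMM", NA_character_,
                                                ifelse(persistent, "persistent",
                                                       "clearing")),
                          severity = severity, random_intercept = u,
                          hazard_pfs = h_pfs, hazard_os = h_os,
                          stringsAsFactors = FALSE),
    observations = data.frame(patient_id = ids[i],
                              time_months = j * cfg$timepoint_spacing_months,
                              phase_index = pidx, log_mu = log_mu,
                              structural_zero = structural,
                              stringsAsFactors = FALSE),
    config = cfg)
  list(cohort = cohort, truth = truth)
}

generate_mrd <- function(ids, stage, timepoints, cfg) {
  rows <- list()
  phase_for <- c(post_induction = "induction", pre_maintenance = "consolidation")
  for (pid in ids[stage == "MM"]) {
    tp <- timepoints[timepoints$patient_id == pid, , drop = FALSE]
    for (lab in names(phase_for)) {
      enum <- tp[tp$phase == phase_for[[lab]], , drop = FALSE]
      if (!nrow(enum)) next
      cnt <- enum$cmmc_count[which.max(enum$time_months)]
      detectable <- runif(1) < plogis(-1.1 + 1.1 * log1p(cnt))
      value <- if (detectable)
        max(cfg$mrd_sensitivity,
            min(3.22, 10^(-4 + 0.8 * log1p(cnt) + rnorm(1, sd = 0.8))))
      else 0
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, timepoint = lab, mrd_value = value,
        detectable = detectable, hemodiluted = runif(1) < 0.3,
        sensitivity = cfg$mrd_sensitivity, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_mrd())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
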