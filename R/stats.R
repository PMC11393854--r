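#' Pairwise correlation matrix with pairwise-complete deletion
#'
#' Computes Pearson or Spearman correlations between every pair of columns,
#' using for each pair the observations complete on both variables. Cells
#' with fewer than `min_pairs` complete pairs, or involving a constant
#' variable, are flagged as `NA` rather than raising an error. P-values use
#' the t-distribution transform of r; for Spearman with n <= 10 and no ties
#' the exact permutation distribution is used instead.
#'
#' @param table data.frame or matrix of numeric observations x variables.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_pairs Minimum complete pairs per reported cell (default 3).
#' @return Object of class `cmmc_cormat`: list with `variables`, symmetric
#'   matrices `r`, `p` and `n_pairs`, and `method`.
#' @export
pairwise_correlations <- function(table, method = c("pearson", "spearman"),
                                  min_pairs = 3) {
  method <- match.arg(method)
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[num]
  vars <- names(table)
  k <- length(vars)
  if (k < 2) validation_error("need at least two numeric variables")
  r <- p <- n_pairs <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k)) {
    n_pairs[i, i] <- sum(!is.na(table[[i]]))
    for (j in seq_len(k)[-seq_len(i)]) {
      ok <- complete.cases(table[[i]], table[[j]])
      n <- sum(ok)
      n_pairs[i, j] <- n_pairs[j, i] <- n
      if (n < max(min_pairs, 3)) next
      x <- table[[i]][ok]; y <- table[[j]][ok]
      if (var(x) == 0 || var(y) == 0) next  # constant variable: flagged NA
      rij <- cor(x, y, method = method)
      r[i, j] <- r[j, i] <- rij
      p[i, j] <- p[j, i] <- cor_pvalue(x, y, rij, method)
    }
  }
  structure(list(variables = vars, r = r, p = p, n_pairs = n_pairs,
                 method = method),
            class = "cmmc_cormat")
}

cor_pvalue <- function(x, y, r, method) {
  n <- length(x)
  if (method == "spearman" && n <= 10 &&
      !anyDuplicated(x) && !anyDuplicated(y)) {
    return(suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value))
  }
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), df = n - 2)
}

#' @export
print.cmmc_cormat <- function(x, digits = 3, ...) {
  cat(sprintf("<cmmc_cormat> %s, %d variables\n", x$method,
              length(x$variables)))
  print(round(x$r, digits))
  invisible(x)
}

#' Kruskal-Wallis rank test between groups
#'
#' Compares the locations of two or more groups by the Kruskal-Wallis
#' mid-rank statistic with tie correction; p-value from the chi-squared
#' distribution with k-1 degrees of freedom.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    validation_error("kruskal_wallis needs a list of >= 2 groups")
  if (any(!vapply(groups, length, integer(1))))
    validation_error("every group must be non-empty")
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the probability-mass rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the probability of the observed table (within a
#' relative tolerance of 1e-7). The odds ratio is the conditional maximum
#' likelihood estimate.
#'
#' @param table 2x2 matrix of non-negative integer counts; all row and
#'   column margins must be >= 1.
#' @return list with `odds_ratio` and `p`.
#' @examples
#' fisher_exact_2x2(matrix(c(6, 9, 19, 6), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    validation_error("table must be 2x2")
  if (any(is.na(table)) || any(table < 0) || any(table %% 1 != 0))
    validation_error("table entries must be non-negative integers")
  if (any(rowSums(table) < 1) || any(colSums(table) < 1))
    validation_error("all margins must be >= 1")
  ft <- fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Random-intercept longitudinal model of CMMC counts
#'
#' Fits a Gaussian linear mixed model to `log(cmmc_count + 1)` with the
#' requested predictors as fixed effects and a per-patient random
#' intercept (REML), mitigating the intra-subject correlation of repeated
#' enumerations. Coefficients are reported on the log scale together with
#' their multiplicative equivalents `exp(beta)` — the fold-change in CMMC
#' count per unit of the predictor. A fixed-effects-only ordinary linear
#' model on the same rows is fitted alongside (this is also the exact
#' mixed-model solution when the random-intercept variance is pinned to
#' zero).
#'
#' @param x A [cmmc_cohort()] (its timepoint table is used) or a data.frame
#'   containing `patient_id`, `cmmc_count` and the predictor columns. When
#'   a cohort is given, `phase_index` (0 = diagnosis/untreated, 1 =
#'   induction, 2 = consolidation, 3 = maintenance/progression) is derived
#'   and available as a predictor.
#' @param predictors Character vector of predictor column names; default
#'   the biomarker panel used for CMMC dynamics (beta2m, albumin,
#'   kappa/lambda ratio, LDH, M-protein, total protein).
#' @return Object of class `cmmc_longfit`: coefficients and
#'   `multiplicative_effects` for the mixed model, `random_intercept_variance`,
#'   `residual_variance`, `scaled_residual_median`, `n_obs`, `n_patients`,
#'   the fixed-effects-only fit under `fixed_only`, dropped (constant)
#'   predictors under `dropped`, and a convergence `status`. Rows with a
#'   missing predictor are dropped listwise.
#' @export
fit_longitudinal_model <- function(x, predictors = c("beta2m", "albumin",
                                                     "kappa_lambda_ratio",
                                                     "ldh", "m_protein",
                                                     "total_protein")) {
  df <- if (inherits(x, "cmmc_cohort")) {
    tp <- x$timepoints
    tp$phase_index <- phase_index(tp$phase)
    tp
  } else as.data.frame(x)
  missing_cols <- setdiff(c("patient_id", "cmmc_count", predictors), names(df))
  if (length(missing_cols))
    format_error(sprintf("missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  df <- df[complete.cases(df[c("cmmc_count", predictors)]), , drop = FALSE]
  if (nrow(df) < 2 || length(unique(df$patient_id)) < 2)
    validation_error("need >= 2 observations from >= 2 patients")
  dropped <- predictors[vapply(df[predictors],
                               function(v) var(as.numeric(v)) == 0, logical(1))]
  kept <- setdiff(predictors, dropped)
  if (!length(kept))
    validation_error("all predictors are constant; no model to fit")
  df$.y <- log(df$cmmc_count + 1)

  fml_fix <- as.formula(paste(".y ~", paste(kept, collapse = " + ")))
  ols <- lm(fml_fix, data = df)
  fixed_only <- list(coefficients = coef(ols)[kept],
                     multiplicative_effects = exp(coef(ols)[kept]))

  fml <- as.formula(paste(".y ~", paste(kept, collapse = " + "),
                          "+ (1 | patient_id)"))
  status <- "converged"
  fit <- tryCatch(lme4::lmer(fml, data = df, REML = TRUE),
                  error = function(e) e, warning = function(w) w)
  if (inherits(fit, "condition")) {
    # fall back to the fixed-effects fit but keep the explicit status
    status <- paste("not_converged:", conditionMessage(fit))
    coefs <- coef(ols)[kept]
    re_var <- NA_real_
    res_var <- summary(ols)$sigma^2
    scaled_med <- median(residuals(ols) / summary(ols)$sigma)
  } else {
    if (length(fit@optinfo$conv$lme4))
      status <- "converged_with_warnings"
    coefs <- lme4::fixef(fit)[kept]
    vc <- as.data.frame(lme4::VarCorr(fit))
    re_var <- vc$vcov[vc$grp == "patient_id"]
    res_var <- vc$vcov[vc$grp == "Residual"]
    scaled_med <- median(residuals(fit, scaled = TRUE))
  }
  structure(list(coefficients = coefs,
                 multiplicative_effects = exp(coefs),
                 random_intercept_variance = re_var,
                 residual_variance = res_var,
                 scaled_residual_median = scaled_med,
                 n_obs = nrow(df),
                 n_patients = length(unique(df$patient_id)),
                 fixed_only = fixed_only,
                 dropped = dropped,
                 transform = "log(count + 1)",
                 status = status),
            class = "cmmc_longfit")
}

#' @export
print.cmmc_longfit <- function(x, ...) {
  cat("Longitudinal CMMC model on", x$transform, "with patient random intercept\n")
  cat(sprintf("  %d observations, %d patients (%s)\n", x$n_obs, x$n_patients,
              x$status))
  tab <- data.frame(log_coef = x$coefficients,
                    fold_change = x$multiplicative_effects)
  print(round(tab, 4))
  cat(sprintf("  random-intercept variance %.4f, residual variance %.4f\n",
              x$random_intercept_variance, x$residual_variance))
  cat(sprintf("  scaled residual median %.4f\n", x$scaled_residual_median))
  if (length(x$dropped))
    cat("  dropped constant predictor(s):", paste(x$dropped, collapse = ", "), "\n")
  cat("  p-values, where reported downstream, are raw (no multiplicity adjustment)\n")
  invisible(x)
}

#' Map treatment phase labels to a numeric phase index
#'
#' @param phase Character vector of phase labels.
#' @return Integer vector: 0 for diagnosis/untreated follow-up, 1 for
#'   induction, 2 for consolidation, 3 for maintenance and progression.
#' @export
phase_index <- function(phase) {
  idx <- c(diagnosis = 0L, untreated_followup = 0L, induction = 1L,
           consolidation = 2L, maintenance = 3L, progression = 3L)
  unname(idx[phase])
}
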