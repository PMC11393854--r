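test_that("pairwise correlations reproduce hand-computed values", {
  x <- c(1, 2, 3); y <- c(1, 4, 9)
  tab <- data.frame(x = x, y = y)
  pear <- pairwise_correlations(tab, "pearson")
  expect_equal(pear$r["x", "y"], 0.98974, tolerance = 1e-4)
  spear <- pairwise_correlations(tab, "spearman")
  expect_equal(spear$r["x", "y"], 1)
  # self-correlation and sign flip
  tab2 <- data.frame(a = x, b = -x)
  m <- pairwise_correlations(tab2, "pearson")
  expect_equal(m$r["a", "a"], 1)
  expect_equal(m$r["a", "b"], -1)
  expect_true(isSymmetric(m$r) && isSymmetric(m$p))
})

test_that("spearman correlation is invariant under monotone transforms", {
  set.seed(501)
  for (rep in 1:10) {
    x <- rnorm(30); y <- x + rnorm(30)
    r0 <- pairwise_correlations(data.frame(x, y), "spearman")$r["x", "y"]
    r1 <- pairwise_correlations(data.frame(x = exp(x), y = y^3 + 5),
                                "spearman")$r["x", "y"]
    expect_equal(r1, r0)
  }
})

test_that("constant variables and short pairs are flagged NA, not errors", {
  tab <- data.frame(x = c(1, 2, 3, 4), cst = rep(5, 4),
                    sparse = c(1, NA, NA, NA))
  m <- pairwise_correlations(tab, "pearson")
  expect_true(is.na(m$r["x", "cst"]))
  expect_true(is.na(m$r["x", "sparse"]))
  expect_equal(m$n_pairs["x", "sparse"], 1)
})

test_that("kruskal-wallis matches the rank-sum formula and is label-symmetric", {
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$H, 0)
  expect_equal(same$p, 1)
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  kw_swapped <- kruskal_wallis(list(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(kw_swapped$H, kw$H)
  expect_error(kruskal_wallis(list(c(1, 2))), class = "cmmcdyn_validation_error")
})

test_that("fisher exact reproduces the response-table p and its symmetries", {
  res <- fisher_exact_2x2(matrix(c(6, 9, 19, 6), 2, byrow = TRUE))
  expect_equal(res$p, 0.042, tolerance = 0.01)
  flat <- fisher_exact_2x2(matrix(5, 2, 2))
  expect_equal(flat$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(flat$p, 1)
  tab <- matrix(c(8, 2, 9, 14), 2, byrow = TRUE)
  p0 <- fisher_exact_2x2(tab)$p
  expect_equal(fisher_exact_2x2(tab[2:1, ])$p, p0)
  expect_equal(fisher_exact_2x2(tab[, 2:1])$p, p0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 2, 3, 4), 2)),
               class = "cmmcdyn_validation_error")
})

test_that("fisher exact agrees with hypergeometric enumeration on random tables", {
  set.seed(502)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(fisher_exact_2x2(tab)$p, fisher_p_enumerated(tab),
                 tolerance = 1e-10)
  }
})

test_that("the longitudinal model recovers an exact log-linear construction", {
  # counts chosen freely; beta2m defined so log(count+1) is exactly
  # alpha + log(5.5) * beta2m -- the fit must return 5.5 and agree with OLS
  set.seed(503)
  n_pat <- 12; n_tp <- 4
  counts <- matrix(rnbinom(n_pat * n_tp, mu = 40, size = 2), n_pat)
  alpha <- -1
  df <- data.frame(
    patient_id = rep(sprintf("p%02d", 1:n_pat), each = n_tp),
    cmmc_count = as.integer(t(counts)),
    stringsAsFactors = FALSE)
  df$beta2m <- (log(df$cmmc_count + 1) - alpha) / log(5.5)
  # the zero-residual design makes summary.lm warn about a perfect fit
  fit <- suppressWarnings(fit_longitudinal_model(df, predictors = "beta2m"))
  expect_equal(unname(fit$multiplicative_effects["beta2m"]), 5.5,
               tolerance = 1e-6)
  ols <- lm(log(cmmc_count + 1) ~ beta2m, data = df)  # independent route
  expect_equal(unname(fit$fixed_only$coefficients["beta2m"]),
               unname(coef(ols)["beta2m"]), tolerance = 1e-10)
  expect_equal(fit$n_obs, n_pat * n_tp)
})

test_that("fixed-effects-only coefficients equal OLS (variance pinned to zero)", {
  gen <- generate_cohort(generator_config(30, seed = 9))
  fit <- fit_longitudinal_model(gen$cohort,
                                predictors = c("beta2m", "m_protein"))
  tp <- gen$cohort$timepoints
  tp <- tp[complete.cases(tp[c("cmmc_count", "beta2m", "m_protein")]), ]
  ols <- lm(log(cmmc_count + 1) ~ beta2m + m_protein, data = tp)
  expect_equal(fit$fixed_only$coefficients,
               coef(ols)[c("beta2m", "m_protein")], tolerance = 1e-10)
  expect_equal(fit$fixed_only$multiplicative_effects,
               exp(fit$fixed_only$coefficients))
})

test_that("a constant predictor is dropped and flagged, not fatal", {
  df <- data.frame(patient_id = rep(c("a", "b"), each = 3),
                   cmmc_count = c(0L, 2L, 5L, 1L, 3L, 8L),
                   beta2m = c(2, 3, 4, 2.5, 3.5, 4.5),
                   ldh = rep(180, 6))
  fit <- fit_longitudinal_model(df, predictors = c("beta2m", "ldh"))
  expect_equal(fit$dropped, "ldh")
  expect_false("ldh" %in% names(fit$coefficients))
  expect_error(fit_longitudinal_model(df, predictors = "ldh"),
               class = "cmmcdyn_validation_error")
})

test_that("the mixed model recovers the random-intercept variance on simulated cohorts", {
  # moderate-size check against the generator's own ground truth
  set.seed(504)
  sds <- replicate(6, {
    seed <- sample.int(1e6, 1)
    gen <- generate_cohort(generator_config(150, seed = seed,
                                            missing_rate = 0))
    tp <- merge(gen$cohort$timepoints, gen$truth$observations,
                by = c("patient_id", "time_months"))
    tp <- tp[!tp$structural_zero, ]
    fit <- fit_longitudinal_model(tp, predictors = c("beta2m", "phase_index"))
    sqrt(fit$random_intercept_variance)
  })
  expect_equal(median(sds), 0.5, tolerance = 0.25)
})
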