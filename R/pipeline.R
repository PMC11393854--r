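#' Run the full CMMC analysis pipeline
#'
#' Orchestrates simulate/read -> coMMstant classification -> baseline
#' stratification -> biomarker statistics -> MRD concordance -> survival
#' contrast -> (optional) single-cell CNA analysis, writing CSV tables, a
#' JSON summary and a structured log into `out_dir`. Every summary value
#' is obtained by calling the corresponding module function on the same
#' inputs; the orchestration layer does no arithmetic of its own.
#' Exclusion accounting (indeterminate classifications, hemodilution
#' exclusions, unpaired MRD records) is logged stage by stage, because
#' group denominators hinge on it.
#'
#' @param config A named list, or a path to a YAML/JSON file holding one.
#'   Recognized keys: `simulate` (logical; when `TRUE`, `generator` is a
#'   list of [generator_config()] arguments), `paths` (list with
#'   `patients`, `timepoints`, optional `mrd`), `cna` (optional list with
#'   `cells`, `bulk` CSV paths), `commstant` (list: `rule`,
#'   `window_phases`), `pairing` (list: `window_months`), `endpoints`
#'   (any of `"pfs"`, `"os"`), `out_dir`, `seed`. Unknown keys are
#'   rejected.
#' @return Invisibly, the summary list (also written as `summary.json`).
#'   Given the same config (including seed) the bundle is bit-identical.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  log_lines <- character()
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      note(stage, paste("FAILED:", conditionMessage(e)))
      writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = cfg$seed)

  ## acquire cohort
  cohort <- run_stage("input", {
    if (isTRUE(cfg$simulate)) {
      gargs <- cfg$generator %||% list()
      gargs$seed <- gargs$seed %||% cfg$seed
      gen <- generate_cohort(do.call(generator_config, gargs))
      write_cohort(gen$cohort, cfg$out_dir)
      note("input", sprintf("simulated %d patients (seed %d)",
                            nrow(gen$cohort$patients), gargs$seed))
      gen$cohort
    } else {
      coh <- read_cohort(cfg$paths$patients, cfg$paths$timepoints,
                         cfg$paths$mrd)
      note("input", sprintf("read %d patients, %d timepoints, %s MRD records",
                            nrow(coh$patients), nrow(coh$timepoints),
                            if (is.null(coh$mrd)) "no" else nrow(coh$mrd)))
      coh
    }
  })

  ## coMMstant classification
  cls <- run_stage("commstant", {
    cls <- classify_cohort_commstant(cohort,
                                     window_phases = cfg$commstant$window_phases,
                                     rule = cfg$commstant$rule)
    write.csv(cls, file.path(cfg$out_dir, "commstant.csv"), row.names = FALSE)
    note("commstant", sprintf("index 1: %d, index 0: %d, indeterminate: %d",
                              sum(cls$index == "1"), sum(cls$index == "0"),
                              sum(cls$index == "indeterminate")))
    cls
  })
  summary$group_sizes <- as.list(table(cls$index))

  ## baseline stratification (per stage)
  summary$stratification <- run_stage("stratify", {
    out <- lapply(c(SMM = "SMM", MM = "MM"), function(stg) {
      b <- baseline_counts(cohort, stages = stg)
      if (!length(b)) return(NULL)
      s <- stratify_by_baseline_median(b)
      note("stratify", sprintf("%s median %.1f: %d high / %d low", stg,
                               s$median, length(s$high), length(s$low)))
      list(median = s$median, n_high = length(s$high), n_low = length(s$low))
    })
    out[!vapply(out, is.null, logical(1))]
  })

  ## response cross-tab (>=VGPR by coMMstant index)
  summary$response <- run_stage("response", {
    pat <- merge(cohort$patients, cls, by = "patient_id")
    pat <- pat[pat$index %in% c("1", "0") & !is.na(pat$best_response), ]
    if (nrow(pat) < 2 || length(unique(pat$index)) < 2) {
      note("response", "skipped: fewer than two classified groups with responses")
      NULL
    } else {
      hi <- pat$best_response %in% c("CR", "VGPR")
      tab <- table(factor(pat$index, c("1", "0")),
                   factor(ifelse(hi, ">=VGPR", "<VGPR"), c(">=VGPR", "<VGPR")))
      ft <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        fisher_exact_2x2(tab) else NULL
      note("response", sprintf(">=VGPR %d/%d (index 1) vs %d/%d (index 0)",
                               tab["1", ">=VGPR"], sum(tab["1", ]),
                               tab["0", ">=VGPR"], sum(tab["0", ])))
      list(table = as.list(as.data.frame(tab)), fisher_p = ft$p %||% NA)
    }
  })

  ## MRD concordance
  summary$mrd <- run_stage("mrd", {
    if (is.null(cohort$mrd) || nrow(cohort$mrd) == 0) {
      note("mrd", "skipped: no MRD table")
      NULL
    } else {
      pairs <- pair_measurements(cohort,
                                 window_months = cfg$pairing$window_months)
      write.csv(as.data.frame(pairs), file.path(cfg$out_dir, "mrd_pairs.csv"),
                row.names = FALSE)
      conc <- concordance(pairs)
      note("mrd", sprintf("%d MRD records: %d paired (%d hemodilution-excluded), %d unpaired; concordance %d/%d",
                          nrow(cohort$mrd), nrow(pairs), conc$n_excluded,
                          nrow(attr(pairs, "unpaired")), conc$n_concordant,
                          conc$n_pairs))
      list(n_pairs = conc$n_pairs, n_concordant = conc$n_concordant,
           fraction_concordant = conc$fraction_concordant,
           n_excluded = conc$n_excluded,
           n_unpaired = nrow(attr(pairs, "unpaired")))
    }
  })

  ## survival contrasts
  summary$survival <- run_stage("survival", {
    out <- list()
    for (ep in cfg$endpoints) {
      res <- tryCatch(survival_by_commstant(cohort, cls, ep),
                      error = function(e) NULL)
      if (is.null(res)) {
        note("survival", sprintf("%s skipped: insufficient groups/events", ep))
        next
      }
      out[[ep]] <- list(hr = res$cox$hr, ci = c(res$cox$ci_lower,
                                                res$cox$ci_upper),
                        logrank_p = res$cox$logrank_p,
                        n = as.list(res$cox$n),
                        events = as.list(res$cox$events))
      note("survival", sprintf("%s HR %.3f (%.3f-%.3f), log-rank p %.4g", ep,
                               res$cox$hr, res$cox$ci_lower, res$cox$ci_upper,
                               res$cox$logrank_p))
    }
    if (length(out)) out else NULL
  })

  ## optional single-cell CNA stage
  summary$cna <- run_stage("cna", {
    if (is.null(cfg$cna)) {
      note("cna", "skipped: no single-cell inputs")
      NULL
    } else {
      tabs <- read_cna_tables(cfg$cna$cells, cfg$cna$bulk)
      calls <- classify_clonality(call_alterations(tabs$cells))
      calls <- detect_emerging(calls, tabs$bulk)
      write.csv(as.data.frame(calls), file.path(cfg$out_dir, "cna_calls.csv"),
                row.names = FALSE)
      pls <- ploidy_summary(tabs$cells)
      note("cna", sprintf("%d calls (%s); main ploidy %d", nrow(calls),
                          paste(names(table(calls$category)),
                                table(calls$category), collapse = ", ",
                                sep = ":"), pls$main_ploidy))
      list(clonality = as.list(table(calls$category)),
           n_emerging = sum(calls$emerging), main_ploidy = pls$main_ploidy)
    }
  })

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))
  invisible(summary)
}

KNOWN_CONFIG_KEYS <- c("simulate", "generator", "paths", "cna", "commstant",
                       "pairing", "endpoints", "out_dir", "seed")

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        config_error("YAML configs need the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) config_error("config must be a list or a file path")
  unknown <- setdiff(names(config), KNOWN_CONFIG_KEYS)
  if (length(unknown))
    config_error(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  config$seed <- as.integer(config$seed %||% 1L)
  config$out_dir <- config$out_dir %||% tempfile("cmmc_run_")
  config$endpoints <- config$endpoints %||% c("pfs", "os")
  if (!all(config$endpoints %in% c("pfs", "os")))
    config_error("endpoints must be a subset of pfs, os")
  config$commstant <- config$commstant %||% list()
  config$commstant$rule <- config$commstant$rule %||% "all_positive"
  config$commstant$window_phases <- config$commstant$window_phases %||%
    COMMSTANT_WINDOW
  config$pairing <- config$pairing %||% list(window_months = NULL)
  if (!isTRUE(config$simulate) &&
      (is.null(config$paths$patients) || is.null(config$paths$timepoints)))
    config_error("either simulate: true or paths$patients/timepoints are required")
  config
}
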