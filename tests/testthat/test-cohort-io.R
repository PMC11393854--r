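test_that("a minimal one-patient, one-timepoint CSV pair reads into a cohort", {
  paths <- write_cohort_csvs(
    minimal_patients("P1"),
    minimal_timepoints("P1", 0, "diagnosis", 5L))
  coh <- read_cohort(paths$patients, paths$timepoints)
  expect_s3_class(coh, "cmmc_cohort")
  expect_equal(nrow(coh$patients), 1)
  expect_equal(nrow(coh$timepoints), 1)
  expect_null(coh$mrd)
})

test_that("validation rejects the documented violations, citing the offender", {
  # negative count, with row number
  tp <- minimal_timepoints("P1", c(0, 3), c("diagnosis", "induction"), c(2L, -3L))
  paths <- write_cohort_csvs(minimal_patients("P1"), tp)
  err <- expect_error(read_cohort(paths$patients, paths$timepoints),
                      class = "cmmcdyn_validation_error")
  expect_match(conditionMessage(err), "row\\(s\\) 2")

  # missing mandatory column, named
  tp_bad <- tp[setdiff(names(tp), "cmmc_count")]
  paths <- write_cohort_csvs(minimal_patients("P1"), tp_bad)
  err <- expect_error(read_cohort(paths$patients, paths$timepoints),
                      class = "cmmcdyn_format_error")
  expect_match(conditionMessage(err), "cmmc_count")

  # orphan patient_id
  paths <- write_cohort_csvs(minimal_patients("P1"),
                             minimal_timepoints("P2", 0, "diagnosis", 1L))
  expect_error(read_cohort(paths$patients, paths$timepoints),
               class = "cmmcdyn_referential_error")

  # duplicated (patient_id, time_months)
  expect_error(cmmc_cohort(minimal_patients("P1"),
                           minimal_timepoints(c("P1", "P1"), c(3, 3),
                                              "induction", c(1L, 2L))),
               class = "cmmcdyn_validation_error")

  # pfs > os
  bad <- minimal_patients("P1"); bad$pfs_months <- 20; bad$os_months <- 10
  expect_error(cmmc_cohort(bad, minimal_timepoints("P1", 0, "diagnosis", 1L)),
               class = "cmmcdyn_validation_error")

  # detectable MRD below sensitivity
  expect_error(cmmc_cohort(minimal_patients("P1"),
                           minimal_timepoints("P1", 0, "diagnosis", 1L),
                           minimal_mrd("P1", value = 1e-7)),
               class = "cmmcdyn_validation_error")
})

test_that("write/read round-trips generated cohorts field-for-field", {
  for (seed in c(11, 12)) {
    gen <- generate_cohort(generator_config(25, seed = seed))
    dir <- withr::local_tempdir()
    paths <- write_cohort(gen$cohort, dir)
    back <- read_cohort(paths["patients"], paths["timepoints"], paths["mrd"])
    expect_equal(back$patients, gen$cohort$patients)
    expect_equal(back$timepoints, gen$cohort$timepoints)
    expect_equal(back$mrd, gen$cohort$mrd)
  }
})

test_that("an empty cohort writes three header-only files", {
  gen <- generate_cohort(generator_config(0, seed = 1))
  dir <- withr::local_tempdir()
  paths <- write_cohort(gen$cohort, dir)
  expect_length(paths, 3)
  for (p in paths) expect_length(readLines(p), 1)
})

test_that("missing biomarkers become empty cells, never the string NA", {
  tp <- minimal_timepoints("P1", 0, "diagnosis", 3L)  # all biomarkers NA
  coh <- cmmc_cohort(minimal_patients("P1"), tp)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  lines <- readLines(paths["timepoints"])
  expect_false(any(grepl("NA", lines, fixed = TRUE)))
})

test_that("the bundled SMM monitoring series loads as 7 patients, 20 timepoints", {
  coh <- example_smm_cohort()
  expect_equal(nrow(coh$patients), 7)
  expect_equal(nrow(coh$timepoints), 20)
  expect_true(all(coh$patients$stage == "SMM"))
})

test_that("CNA tables read into profiles; bad tokens and duplicates are rejected", {
  dir <- withr::local_tempdir()
  cells_csv <- file.path(dir, "cells.csv")
  bulk_csv <- file.path(dir, "bulk.csv")
  writeLines(c("cell_id,patient_id,chrom,arm,state,ploidy",
               "c1,PA,1,q,amp,4.1",
               "c1,PA,13,q,del,4.1",
               "c2,PA,1,q,gain,3.9",
               "c2,PA,13,q,del,3.9"), cells_csv)
  writeLines(c("patient_id,chrom,arm,state,tumor_fraction,ploidy",
               "PA,1,q,gain,0.78,2",
               "PA,13,q,del,0.78,2"), bulk_csv)
  tabs <- read_cna_tables(cells_csv, bulk_csv)
  expect_equal(nrow(tabs$cells$ploidy), 2)
  expect_equal(nrow(tabs$cells$states), 4)
  expect_equal(tabs$bulk$tumor_fraction, 0.78)

  writeLines(c("cell_id,patient_id,chrom,arm,state,ploidy",
               "c1,PA,1,q,loss,4"), cells_csv)  # dialect fixes del, not loss
  expect_error(read_cna_tables(cells_csv, bulk_csv),
               class = "cmmcdyn_format_error")

  writeLines(c("cell_id,patient_id,chrom,arm,state,ploidy",
               "c1,PA,1,q,amp,4", "c1,PA,1,q,gain,4"), cells_csv)
  expect_error(read_cna_tables(cells_csv, bulk_csv),
               class = "cmmcdyn_validation_error")
})

test_that("a uniform 19-cell table reproduces all-cell 1q gain and 13 deletion", {
  states <- do.call(rbind, lapply(sprintf("c%02d", 1:19), function(id)
    data.frame(cell_id = id, patient_id = "P4",
               chrom = c("1", "13", "13"), arm = c("q", "q", "p"),
               state = c("amp", "del", "del"), stringsAsFactors = FALSE)))
  cells <- cell_profiles(states, data.frame(cell_id = sprintf("c%02d", 1:19),
                                            ploidy = 2))
  calls <- call_alterations(cells)
  expect_true(all(calls$n_cells == 19))
  expect_setequal(paste(calls$chrom, calls$arm, calls$direction),
                  c("1 q gain", "13 q loss", "13 p loss"))
})
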