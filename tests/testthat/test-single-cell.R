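two_cell_profiles <- function() {
  states <- data.frame(
    cell_id = c("c1", "c2"), patient_id = "P",
    chrom = c("8", "8"), arm = c("q", "q"),
    state = c("gain", "del"), stringsAsFactors = FALSE)
  cell_profiles(states, data.frame(cell_id = c("c1", "c2"), ploidy = 2))
}

test_that("alteration calls collapse gain/amp, ignore neutral, and split directions", {
  states <- data.frame(
    cell_id = c("c1", "c1", "c2", "c2", "c3"), patient_id = "P",
    chrom = c("1", "13", "1", "13", "1"),
    arm = c("q", "q", "q", "q", "q"),
    state = c("amp", "del", "gain", "neutral", "amp"),
    stringsAsFactors = FALSE)
  cells <- cell_profiles(states, data.frame(cell_id = c("c1", "c2", "c3"),
                                            ploidy = 4))
  calls <- call_alterations(cells)
  g1q <- calls[calls$chrom == "1" & calls$direction == "gain", ]
  expect_equal(g1q$n_cells, 3)  # amp and gain are one identity
  expect_equal(g1q$n_total, 3)
  d13 <- calls[calls$chrom == "13", ]
  expect_equal(d13$n_cells, 1)  # neutral contributes nothing

  # all-neutral cells: empty call set
  allneut <- cell_profiles(
    data.frame(cell_id = "c1", patient_id = "P", chrom = "2", arm = "p",
               state = "neutral", stringsAsFactors = FALSE),
    data.frame(cell_id = "c1", ploidy = 2))
  expect_equal(nrow(call_alterations(allneut)), 0)

  # opposite directions on the same arm are distinct calls
  both <- call_alterations(two_cell_profiles())
  expect_equal(nrow(both), 2)
  expect_setequal(both$direction, c("gain", "loss"))

  # mixed patients rejected
  bad <- data.frame(cell_id = c("c1", "c2"), patient_id = c("A", "B"),
                    chrom = "1", arm = "q", state = "gain",
                    stringsAsFactors = FALSE)
  expect_error(call_alterations(
    cell_profiles(bad, data.frame(cell_id = c("c1", "c2"), ploidy = 2))),
    class = "cmmcdyn_validation_error")
})

test_that("clonality categories follow the 19-cell thresholds and partition calls", {
  calls <- data.frame(chrom = c("1", "11", "2", "17"),
                      arm = c("q", "q", "p", "p"),
                      direction = c("gain", "gain", "gain", "loss"),
                      n_cells = c(19L, 17L, 3L, 2L), n_total = 19L,
                      fraction = c(19, 17, 3, 2) / 19)
  got <- classify_clonality(calls)
  expect_equal(got$category, c("clonal", "clonal", "subclonal", "rare"))
  expect_true(all(table(got$category)[c("clonal", "subclonal", "rare")] ==
                    c(2, 1, 1)))
  # every call gets exactly one category
  expect_false(anyNA(got$category))
})

test_that("emerging alterations are those absent from the bulk, including opposite direction", {
  bulk <- bulk_profile("P", data.frame(chrom = c("1", "8"), arm = c("q", "q"),
                                       state = c("gain", "gain")),
                       tumor_fraction = 0.5, ploidy = 2)
  calls <- data.frame(chrom = c("1", "11", "8"), arm = c("q", "q", "q"),
                      direction = c("gain", "gain", "loss"),
                      n_cells = c(5L, 5L, 3L), n_total = 5L,
                      fraction = c(1, 1, 0.6))
  attr(calls, "patient_id") <- "P"
  got <- detect_emerging(calls, bulk)
  expect_equal(got$emerging, c(FALSE, TRUE, TRUE))

  attr(calls, "patient_id") <- "OTHER"
  expect_error(detect_emerging(calls, bulk),
               class = "cmmcdyn_validation_error")
})

test_that("bulk/cell overlap uses majority calls and the Jaccard index", {
  bulk <- bulk_profile("P", data.frame(chrom = c("1", "13"), arm = c("q", "q"),
                                       state = c("gain", "del")),
                       tumor_fraction = 0.5, ploidy = 2)
  calls_same <- data.frame(chrom = c("1", "13"), arm = c("q", "q"),
                           direction = c("gain", "loss"),
                           n_cells = c(9L, 9L), n_total = 10L,
                           fraction = 0.9)
  attr(calls_same, "patient_id") <- "P"
  expect_equal(compare_bulk_cells(calls_same, bulk)$jaccard, 1)

  calls_disjoint <- data.frame(chrom = c("5", "7"), arm = c("p", "q"),
                               direction = "gain", n_cells = 8L,
                               n_total = 10L, fraction = 0.8)
  attr(calls_disjoint, "patient_id") <- "P"
  expect_equal(compare_bulk_cells(calls_disjoint, bulk)$jaccard, 0)

  # sub-majority calls do not enter the cell-side set
  calls_minor <- calls_same
  calls_minor$fraction <- c(0.9, 0.3)
  cmp <- compare_bulk_cells(calls_minor, bulk)
  expect_equal(cmp$shared, "1 q gain")
  expect_equal(cmp$bulk_only, "13 q loss")
  expect_equal(cmp$jaccard, 0.5)
})

test_that("main ploidy is the mode of rounded ploidies with ties going low", {
  mk <- function(pl) cell_profiles(
    data.frame(cell_id = character(), patient_id = character(),
               chrom = character(), arm = character(), state = character()),
    data.frame(cell_id = paste0("c", seq_along(pl)), ploidy = pl))
  expect_equal(ploidy_summary(mk(c(4.1, 3.9, 4.0)))$main_ploidy, 4)
  expect_equal(ploidy_summary(mk(2.0))$main_ploidy, 2)
  tie <- ploidy_summary(mk(c(2, 2, 4, 4)))
  expect_equal(tie$main_ploidy, 2)
  expect_true(tie$tie)
})

test_that("all outputs are invariant to cell ordering", {
  ex <- generate_single_cell_experiment(
    n_cells = 12,
    bulk_alterations = data.frame(chrom = "1", arm = "q", direction = "gain"),
    subclone_spec = list(list(alterations = data.frame(chrom = "6", arm = "p",
                                                       direction = "loss"),
                              fraction = 0.4)),
    emerging_spec = data.frame(chrom = "11", arm = "q", direction = "gain",
                               n_cells = 3L),
    seed = 77)
  cells <- ex$cells
  perm <- sample(nrow(cells$states))
  shuffled <- cell_profiles(cells$states[perm, ],
                            cells$ploidy[sample(nrow(cells$ploidy)), ])
  c1 <- call_alterations(cells)
  c2 <- call_alterations(shuffled)
  key <- function(d) d[order(d$chrom, d$arm, d$direction),
                       c("chrom", "arm", "direction", "n_cells")]
  expect_equal(key(as.data.frame(c1)), key(as.data.frame(c2)),
               ignore_attr = TRUE)
  expect_equal(ploidy_summary(cells)$main_ploidy,
               ploidy_summary(shuffled)$main_ploidy)
})

test_that("pooled single-cell yields reproduce the published workup rates", {
  y <- example_single_cell_yields()
  rates <- single_cell_yield_rates(y)
  expect_equal(round(rates$redetection_pct), 32)
  expect_equal(round(rates$qc_pct), 80)
  expect_equal(round(rates$aberrant_pct), 94)
  bad <- y; bad$recovered[1] <- bad$enumerated[1] + 5
  expect_error(single_cell_yield_rates(bad),
               class = "cmmcdyn_validation_error")
})
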