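as_alteration_df <- function(x, what) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0))
    return(data.frame(chrom = character(), arm = character(),
                      direction = character(), stringsAsFactors = FALSE))
  x <- check_columns(as.data.frame(x), c("chrom", "arm", "direction"), what)
  x$chrom <- as.character(x$chrom)
  check_domain(x$direction, c("gain", "loss"), paste(what, "direction"),
               allow_na = FALSE)
  x
}

alteration_key <- function(df) paste(df$chrom, df$arm, df$direction)

direction_state <- function(direction) {
  c(gain = "gain", loss = "del")[direction]
}

#' Generate a synthetic single-cell copy-number experiment
#'
#' Builds per-cell arm-level profiles from a known clonal architecture:
#' every cell carries the bulk (truncal) alterations; sub-clones add
#' their private alteration sets to cells sampled according to the mixing
#' fractions; emerging alterations — absent from the bulk profile by
#' requirement — are placed in exactly the specified number of cells.
#' The construction therefore fixes the answer every downstream operation
#' should recover.
#'
#' @param n_cells Number of cells (>= 1).
#' @param bulk_alterations data.frame with columns `chrom`, `arm`,
#'   `direction` (`gain`/`loss`): the truncal set, also the bulk profile.
#' @param subclone_spec list of `list(alterations = <data.frame>,
#'   fraction = <mixing fraction>)`; fractions must sum to <= 1, the
#'   remainder of cells carry only the truncal set.
#' @param emerging_spec data.frame with columns `chrom`, `arm`,
#'   `direction`, `n_cells`: each alteration is planted in exactly
#'   `n_cells` cells; must be disjoint from `bulk_alterations`.
#' @param ploidy True ploidy; per-cell ploidies are drawn N(ploidy,
#'   `ploidy_sd`).
#' @param ploidy_sd Measurement spread of per-cell ploidy (0 for exact).
#' @param tumor_fraction Tumor fraction recorded on the bulk profile.
#' @param patient_id Patient label shared by cells and bulk.
#' @param seed Integer seed; identical calls are bit-identical.
#' @return list with `cells` ([cell_profiles()]), `bulk`
#'   ([bulk_profile()]) and `truth` (subclone assignment per cell, the
#'   emerging set, the truncal set).
#' @examples
#' ex <- generate_single_cell_experiment(
#'   n_cells = 19,
#'   bulk_alterations = data.frame(chrom = c("1", "13", "13"),
#'                                 arm = c("q", "q", "p"),
#'                                 direction = c("gain", "loss", "loss")),
#'   emerging_spec = data.frame(chrom = "11", arm = "q",
#'                              direction = "gain", n_cells = 19))
#' @export
generate_single_cell_experiment <- function(n_cells,
                                            bulk_alterations,
                                            subclone_spec = list(),
                                            emerging_spec = NULL,
                                            ploidy = 4,
                                            ploidy_sd = 0.08,
                                            tumor_fraction = 0.78,
                                            patient_id = "SIM_SC",
                                            seed = 1L) {
  if (n_cells < 1 || n_cells %% 1 != 0)
    config_error("n_cells must be a positive integer")
  bulk_alt <- as_alteration_df(bulk_alterations, "bulk alterations")
  emerging <- as_alteration_df(emerging_spec, "emerging alterations")
  if (!is.null(emerging_spec)) {
    emerging$n_cells <- as.data.frame(emerging_spec)$n_cells
    if (any(is.na(emerging$n_cells)) || any(emerging$n_cells < 1) ||
        any(emerging$n_cells > n_cells))
      config_error("emerging n_cells must lie in [1, n_cells]")
  } else emerging$n_cells <- integer()
  if (length(intersect(alteration_key(emerging), alteration_key(bulk_alt))))
    config_error("emerging alterations must be disjoint from the bulk set")
  fracs <- vapply(subclone_spec, function(s) s$fraction, numeric(1))
  if (length(fracs) && (any(fracs < 0) || sum(fracs) > 1))
    config_error("subclone mixing fractions must be >= 0 and sum to <= 1")

  set.seed(as.integer(seed))
  cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
  probs <- c(fracs, 1 - sum(fracs))  # last = truncal-only base clone
  assignment <- sample.int(length(probs), n_cells, replace = TRUE, prob = probs)

  per_cell <- lapply(seq_len(n_cells), function(k) {
    alt <- bulk_alt
    if (assignment[k] <= length(subclone_spec))
      alt <- rbind(alt, as_alteration_df(
        subclone_spec[[assignment[k]]]$alterations, "subclone alterations"))
    alt[!duplicated(alteration_key(alt)), , drop = FALSE]
  })
  if (nrow(emerging)) {
    for (r in seq_len(nrow(emerging))) {
      carriers <- sample.int(n_cells, emerging$n_cells[r])
      for (k in carriers)
        per_cell[[k]] <- rbind(per_cell[[k]],
                               emerging[r, c("chrom", "arm", "direction")])
    }
  }
  state_rows <- lapply(seq_len(n_cells), function(k) {
    alt <- per_cell[[k]]
    alt <- alt[!duplicated(alteration_key(alt)), , drop = FALSE]
    if (!nrow(alt)) return(NULL)
    data.frame(cell_id = cell_ids[k], patient_id = patient_id,
               chrom = alt$chrom, arm = alt$arm,
               state = direction_state(alt$direction),
               stringsAsFactors = FALSE)
  })
  state_rows <- state_rows[!vapply(state_rows, is.null, logical(1))]
  states <- if (length(state_rows))
    do.call(rbind, c(state_rows, list(make.row.names = FALSE)))
  else
    data.frame(cell_id = character(), patient_id = character(),
               chrom = character(), arm = character(),
               state = character(), stringsAsFactors = FALSE)
  ploidies <- data.frame(cell_id = cell_ids,
                         ploidy = pmax(ploidy + rnorm(n_cells, sd = ploidy_sd),
                                       0.5))
  cells <- cell_profiles(states, ploidies)
  bulk <- bulk_profile(patient_id,
                       data.frame(chrom = bulk_alt$chrom, arm = bulk_alt$arm,
                                  state = direction_state(bulk_alt$direction),
                                  stringsAsFactors = FALSE),
                       tumor_fraction = tumor_fraction, ploidy = ploidy)
  subclone_label <- c(paste0("subclone_", seq_along(subclone_spec)), "base")
  truth <- list(subclones = data.frame(cell_id = cell_ids,
                                       subclone = subclone_label[assignment],
                                       stringsAsFactors = FALSE),
                emerging = emerging, truncal = bulk_alt)
  list(cells = cells, bulk = bulk, truth = truth)
}
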