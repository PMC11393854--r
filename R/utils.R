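# Internal helpers: classed errors and seed substreams.

cmmc_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cmmcdyn_error")))
}

format_error <- function(msg) cmmc_error(msg, "cmmcdyn_format_error")
validation_error <- function(msg) cmmc_error(msg, "cmmcdyn_validation_error")
referential_error <- function(msg) cmmc_error(msg, "cmmcdyn_referential_error")
config_error <- function(msg) cmmc_error(msg, "cmmcdyn_config_error")

#' Derive independent sub-seeds from one master seed
#'
#' Expands a single integer seed into `n` sub-seeds, one per generation
#' stage, so that adding a stage never perturbs the draws of earlier stages.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @keywords internal
substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)
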