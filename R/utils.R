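# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; reported percentages follow the
#' conventional half-up rule (e.g. 68.745 -> 68.7 vs 39.054 -> 39.1 at one
#' decimal place), so tables are formatted with this helper instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(2.5, 3.45), c(0, 1))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() wrappers so callers can distinguish bad configuration from
# violated data contracts.
config_error <- function(msg) {
  stop(errorCondition(msg, class = c("hybridaction_config_error", "error")))
}

contract_error <- function(msg) {
  stop(errorCondition(msg, class = c("hybridaction_contract_error", "error")))
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    config_error(sprintf("'%s' must be a single finite number", name))
  }
  if (x < min) {
    config_error(sprintf("'%s' must be >= %s", name, format(min)))
  }
  invisible(x)
}

# Deterministic per-stage seed substreams derived from one master seed, so
# that e.g. resampling counts does not perturb the gene models.  Offsets are
# fixed; everything stays below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(
    models = 101L, modes = 211L, baseline = 307L, counts = 401L,
    go = 503L, pipeline = 601L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown seed stage: ", stage)
  }
  (as.integer(seed) %% 1000000007L + offsets[[stage]] * 9973L) %% 2147483647L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Write a tab-separated table
#'
#' Plain `write.table()` wrapper with the conventions used throughout the
#' package (no quoting, no row names, tab separator).
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read a tab-separated table
#'
#' @param path input file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE
  )
}
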