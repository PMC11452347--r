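#' @importFrom rlang abort warn %||%
#' @importFrom stats p.adjust pnorm quantile rlnorm rmultinom rnbinom runif setNames
#' @importFrom utils combn
NULL

#' Derive a stage-specific random seed from a master seed
#'
#' Each pipeline stage draws from its own stream, derived deterministically
#' from the master seed and the stage name, so adding or reordering stages
#' never perturbs the draws of earlier stages.
#'
#' @param seed Master seed (single non-negative integer).
#' @param stage Stage name (single string).
#' @return A single integer in `[0, 2^31)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage), length(stage) == 1L)
  m <- 2^31 - 1
  h <- (abs(seed) %% m)
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  as.integer(h)
}

## run `code` under a stage-derived seed, restoring RNG state afterwards
with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(stage_seed(seed, stage), code)
}

#' Parse a "region:subtype" group label
#'
#' @param x A string like `"ME:pericyte"`.
#' @return A list with elements `region` and `subtype`.
#' @export
parse_group <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || any(!nzchar(parts))) {
    abort(sprintf("group label %s is not of the form 'region:subtype'", dQuote(x)))
  }
  list(region = parts[[1]], subtype = parts[[2]])
}

## barcodes of cells belonging to one (region, subtype) group
group_barcodes <- function(cells, region, subtype) {
  bc <- cells$barcode[cells$region == region & cells$subtype == subtype]
  if (length(bc) == 0L) {
    abort(sprintf("no cells in group %s:%s", region, subtype))
  }
  bc
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
is_prop <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x < 1
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
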