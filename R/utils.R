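#' @import data.table
#' @importFrom stats pbinom runif rnorm setNames
#' @importFrom utils head tail
NULL

# Canonical rank ladder, shallow to deep. "organism" is the leaf level used
# for sequenced strains hanging under a species node.
CANONICAL_RANKS <- c("superkingdom", "phylum", "class", "order",
                     "family", "genus", "species")
ALL_LEVELS <- c(CANONICAL_RANKS, "organism")

#' Canonical taxonomic ranks
#'
#' The seven canonical ranks used for per-rank accounting, ordered from the
#' shallowest (superkingdom) to the deepest (species). The extra leaf level
#' `"organism"` denotes individual sequenced strains.
#'
#' @param with_organism if `TRUE`, append the `"organism"` leaf level.
#' @return character vector of rank names, shallow to deep.
#' @export
#' @examples
#' canonical_ranks()
canonical_ranks <- function(with_organism = FALSE) {
  if (with_organism) ALL_LEVELS else CANONICAL_RANKS
}

rank_depth <- function(rank) {
  match(rank, ALL_LEVELS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero for positive
#' input (0.05 -> 0.1), matching how attribution percentages are reported.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

stop_input <- function(...) stop(..., call. = FALSE)
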