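#' @importFrom methods new validObject is slot
#' @importFrom stats as.dist hclust cor
#' @importFrom utils read.delim write.table
NULL

#' Round half away from zero
#'
#' Nearest-integer rounding in which exact halves move away from zero
#' (0.5 -> 1, -0.5 -> -1), the convention used for all reported
#' percentages. Base \code{round()} rounds halves to even and is not used
#' for report output.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' roundHalfUp(c(22.47, 16.29, 29.21, 0.5, -0.5))
roundHalfUp <- function(x) {
  trunc(x + 0.5 * sign(x))
}

## Run an expression under a fixed RNG seed without disturbing the caller's
## RNG state. All stochastic operations in the package route through this.
withSeed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

## Internal logging helper: every filter/threshold application reports
## before/after counts so that "which rule removed what" is auditable.
logCounts <- function(stage, before, after, verbose = getOption("PolyProfile.verbose", FALSE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %d -> %d (removed %d)", stage, before, after, before - after))
  }
  invisible(NULL)
}

## The three cell states of a presence matrix.
PRESENT <- "1"
ABSENT  <- "0"
PUTATIVE <- "P"
validStates <- c(PRESENT, ABSENT, PUTATIVE)

## Canonical subunit order used throughout (RBBP carried but never used for
## complex completeness).
coreSubunits <- function() c("RING1", "PCGF", "EZH", "EED", "SUZ12", "RBBP")
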