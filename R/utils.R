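#' Taxonomic analysis groups
#'
#' The five analysis groups every taxon is assigned to: the focal lineage
#' (\code{SELF}), its vertical relatives (\code{KIN}, metazoans and fungi for a
#' choanoflagellate focal genome), candidate donors (\code{PROKARYOTE} and
#' \code{ALGA}, the latter sensu lato), and all remaining eukaryotes
#' (\code{OTHER_EUK}).
#'
#' @format A character vector of length five.
#' @export
GROUP_LEVELS <- c("SELF", "KIN", "PROKARYOTE", "ALGA", "OTHER_EUK")

#' Phyletic distribution patterns
#'
#' Labels for the taxonomic distribution of a gene's homologs (self-group hits
#' excluded): restricted to prokaryotes, to algae, to both, broad, or absent.
#'
#' @format A character vector of length five.
#' @export
PATTERN_LEVELS <- c("PROK_ONLY", "ALGA_ONLY", "PROK_ALGA_ONLY", "BROAD",
                    "NO_HOMOLOGY")

DONOR_LEVELS <- c("ALGA", "BACTERIA", "EITHER")
STATUS_LEVELS <- c("ACCEPTED", "REJECTED", "NO_CALL")
FLAG_LEVELS <- c("predicted", "not_predicted", "not_run")

#' Round half away from zero
#'
#' Decimal rounding where ties go up (\code{0.05 -> 0.1}), matching how
#' percentages are conventionally printed in genome-survey tables, unlike
#' \code{\link[base]{round}} which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return \code{x} rounded to \code{digits} places, ties away from zero.
#' @examples
#' roundHalfUp(43.523, 1) # 43.5
#' roundHalfUp(2.25, 1)   # 2.3
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## cheap polynomial digest for file headers (reproducibility stamp only)
.digest <- function(s) {
  h <- 7
  for (b in utf8ToInt(paste(s, collapse = "\n"))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

## evaluate expr with a local RNG seed, restoring global RNG state afterwards
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
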