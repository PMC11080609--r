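#' Round half away from zero
#'
#' Commercial rounding used for repeat binning and reported descriptive
#' statistics: exact halves move away from zero (`round2(0.5) == 1`,
#' `round2(-0.5) == -1`), unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_half_away(2.215, 2) # 2.22
#' round_half_away(-0.5)    # -1
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  # small cushion absorbs binary representation error of decimal halves
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Supported polyglutamine loci
#'
#' @return character vector of the four ataxin genes handled by the package.
#' @export
supported_genes <- function() c("ATXN1", "ATXN2", "ATXN3", "ATXN7")

# disease group label <-> locus
.group_gene <- c(SCA1 = "ATXN1", SCA2 = "ATXN2", SCA3 = "ATXN3", SCA7 = "ATXN7")
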