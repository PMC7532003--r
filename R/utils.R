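#' Round half away from zero
#'
#' Rounding convention used throughout the shift statistics: ties at .5 are
#' rounded away from zero (so 0.5 -> 1 and -0.5 -> -1), unlike base
#' [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @export
#' @examples
#' round_half_away(c(0.5, -0.5, 1.5, -2.5))
round_half_away <- function(x) {
  trunc(abs(x) + 0.5) * sign(x)
}

#' Integer percentage of a count over a denominator
#'
#' Reporting convention for headline percentages: 100 * num / den rounded
#' half-away-from-zero to the nearest whole percent.
#'
#' @param num numerator count(s).
#' @param den denominator count(s).
#' @return integer percentage(s).
#' @export
#' @examples
#' percent_of(462, 605)  # 76
percent_of <- function(num, den) {
  stopifnot(all(den > 0))
  as.integer(round_half_away(100 * num / den))
}

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (ACGT).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Length of the leading run of a given base
#'
#' @param x character vector of sequences.
#' @param base single character, the base whose leading run is measured.
#' @return integer vector of run lengths.
#' @keywords internal
leading_run <- function(x, base = "A") {
  nchar(sub(paste0("^(", base, "*).*$"), "\\1", x))
}

# Derive a stage-specific RNG seed from a user seed; kept within 32-bit range.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1800000000L) + as.integer(stage)
}
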