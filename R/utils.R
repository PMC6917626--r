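#' @keywords internal
"_PACKAGE"

#' @importFrom stats rbinom rpois runif setNames hclust as.dist
#' @importFrom utils write.table read.delim head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Round half-up
#'
#' Rounds with ties away from zero at the given number of decimals, the
#' convention used for all printed percentages in pipeline reports (base R
#' `round()` uses banker's rounding, which differs at .x5 boundaries).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(0.15, 1) # 0.2, where round(0.15, 1) gives 0.1
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with report rounding
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimals (default 1, matching report conventions).
#' @return percentage rounded half-up; `NA` when the denominator is zero.
#' @export
#' @examples
#' pct(633, 931) # 68.0
pct <- function(num, den, digits = 1) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, digits))
}

#' Reverse-complement of DNA strings
#'
#' @param x character vector of DNA sequences (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character scalars of equal length.
#' @return integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming() requires equal-length strings")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## split a character vector of equal-length sequences into a character matrix
## (rows = sequences, cols = positions)
seq_char_matrix <- function(x) {
  n <- unique(nchar(x))
  if (length(n) != 1L) stop("sequences must have equal length")
  matrix(unlist(strsplit(x, ""), use.names = FALSE),
         nrow = length(x), ncol = n, byrow = TRUE)
}

## uncorrected p-distance between two equal-length ungapped sequences
p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("sequences must have equal length")
  mean(ca != cb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## safe lookup in a (possibly NULL) named vector/list
lookup <- function(v, key, default = NA) {
  if (is.null(v) || !key %in% names(v)) default else v[[key]]
}
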