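#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats predict
"_PACKAGE"

## The 20 standard amino acids in fixed alphabetical order; every residue
## composition / property vector in the package uses this ordering.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## DSSP secondary-structure states (coil/blank is carried as "-")
SS7 <- c("H", "B", "E", "G", "I", "T", "S")

## One-hot bit order for secondary structure, most- to least-significant,
## so that H -> 0000001, B -> 0000010, ..., S -> 1000000.
SS_BIT_ORDER <- c("S", "T", "I", "G", "E", "B", "H")

#' Normalize an amino-acid sequence to the 20-letter alphabet plus 'X'
#'
#' Upper-cases the sequence and collapses every non-standard letter
#' (B, Z, J, U, O, '*', gaps, ...) to `'X'`. `'X'` arising this way is
#' treated identically to boundary-padding `'X'` by every encoder.
#'
#' @param x character vector of sequences.
#' @return character vector over `A..Y` and `X`.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(x)
  gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "X", x)
}

seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
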