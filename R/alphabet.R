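#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in alphabetical one-letter-code order
#' (A, C, D, ..., Y).  Every frequency, joint-frequency and weight array in
#' the package indexes its residue dimension(s) in this fixed order, and the
#' flattened (position, residue) token layout used by the attention model
#' follows it as well.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Reduced alphabets for small exhaustive tests
#'
#' Statistics code is generic in the alphabet size; tests use the first
#' `n` letters of [AA_ALPHABET] so exhaustive enumeration oracles stay cheap.
#'
#' @param n alphabet size, between 2 and 20.
#' @return Character vector of the first `n` canonical letters.
#' @export
aa_alphabet <- function(n = 20L) {
  n <- as.integer(n)
  if (n < 2L || n > 20L) stop("alphabet size must be in [2, 20]")
  AA_ALPHABET[seq_len(n)]
}
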