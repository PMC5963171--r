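# Residue alphabet conventions shared across the package.

# Classic column order used by published substitution-matrix files.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ambiguity codes retained by parsers but excluded from all counting.
AA_AMBIGUOUS <- c("B", "Z", "X")

#' The 20-residue amino-acid alphabet
#'
#' Returns the twenty standard amino-acid one-letter codes in the classic
#' substitution-matrix column order (A R N D C Q E G H I L K M F P S T W Y V).
#' All pair counting, frequency models and matrix files in this package use
#' this order; ambiguity letters (B, Z, X) and unknown placeholders are
#' preserved by the parsers but never counted.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_ALPHABET

# Split a residue string into single characters (uppercased).
.split_residues <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# Character matrix (rows = sequences) from a block's residue strings.
.block_char_matrix <- function(block) {
  do.call(rbind, strsplit(toupper(block$rows), "", fixed = TRUE))
}
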