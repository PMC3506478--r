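## Alphabets, genetic code and empirical model constants.

#' @keywords internal
NUCLEOTIDES <- c("A", "C", "G", "T")

#' @keywords internal
AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## All 64 codons in T,C,A,G base order at each position (the order the
## standard-table translation string below is written in).
.codon_base_order <- c("T", "C", "A", "G")
ALL_CODONS <- local({
  g <- expand.grid(p3 = .codon_base_order, p2 = .codon_base_order,
                   p1 = .codon_base_order, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
})

## Standard genetic code (translation table 1; identical to table 11 for
## all sense codons).
.standard_code_aa <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "")[[1]]
names(.standard_code_aa) <- ALL_CODONS

#' Sense codons of the standard genetic code
#'
#' The 61 non-stop codons, in a fixed order used throughout for codon
#' state spaces.
#' @keywords internal
SENSE_CODONS <- ALL_CODONS[.standard_code_aa != "*"]

STOP_CODONS <- ALL_CODONS[.standard_code_aa == "*"]

#' Translate codons to amino acids (standard genetic code)
#'
#' @param codons character vector of 3-letter codons (T/C/A/G).
#' @return character vector of one-letter amino acids; `"*"` for stop,
#'   `NA` for codons containing gaps or ambiguity symbols.
#' @export
translate_codons <- function(codons) {
  aa <- unname(.standard_code_aa[toupper(codons)])
  aa
}

#' Genetic code table
#'
#' @return data.frame with columns `codon`, `aa`, `is_stop`.
#' @export
genetic_code <- function() {
  data.frame(codon = ALL_CODONS,
             aa = unname(.standard_code_aa),
             is_stop = unname(.standard_code_aa == "*"),
             stringsAsFactors = FALSE)
}

## Jones-Taylor-Thornton (1992) amino-acid exchangeabilities (lower
## triangle, ARNDCQEGHILKMFPSTWYV order) and equilibrium frequencies, as
## published and distributed with standard phylogenetics software.
.jtt_lower <- c(
 58, 54, 81, 56, 57, 105, 179, 27, 36, 30,
 35, 54, 15, 194, 378, 475, 9, 11, 298, 45,
 16, 113, 310, 29, 137, 328, 22, 38, 646, 44,
 5, 74, 101, 64, 126, 20, 17, 528, 34, 86,
 58, 81, 391, 47, 12, 263, 30, 10, 15, 503,
 232, 8, 70, 16, 10, 49, 767, 130, 112, 11,
 7, 26, 15, 4, 15, 59, 38, 4, 46, 31,
 9, 5, 59, 69, 17, 23, 7, 31, 78, 14,
 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
 292, 43, 4, 164, 53, 51, 18, 24, 20, 119,
 26, 12, 9, 181, 18, 5, 18, 30, 32, 10,
 7, 45, 23, 6, 6, 27, 14, 5, 24, 201,
 33, 55, 8, 47, 16, 56, 45, 33, 40, 115,
 73, 46, 8, 573, 11, 229, 21, 479, 89, 10,
 40, 245, 9, 32, 961, 14, 388, 248, 102, 59,
 25, 52, 24, 180, 65, 4, 21, 47, 103, 10,
 8, 14, 43, 16, 29, 226, 24, 18, 323, 17,
 92, 12, 53, 536, 62, 285, 118, 6, 10, 23,
 477, 35, 63, 38, 12, 21, 112, 71, 25, 16)
.jtt_freq <- c(
 0.07674792325, 0.05169094831, 0.04264495736, 0.05154394846, 0.0198029802, 0.04075195925, 0.06182993817,
 0.07315192685, 0.02294397706, 0.05376094624, 0.0919039081, 0.05867594132, 0.02382597617, 0.04012595987,
 0.0509009491, 0.06876493124, 0.05856494144, 0.01426098574, 0.0321019679, 0.066004934)

.jtt_env <- new.env(parent = emptyenv())
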