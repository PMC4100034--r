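# Genetic-code lookup tables used throughout the package. The standard code
# is taken from Biostrings; everything here is derived from it once at
# install time so downstream code never re-parses codon strings.

#' @importFrom Biostrings GENETIC_CODE
CODON_TO_AA <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

#' All 64 codons in fixed lexicographic order
#' @keywords internal
ALL_CODONS <- names(CODON_TO_AA)

#' The three stop codons
#' @keywords internal
STOP_CODONS <- names(CODON_TO_AA)[CODON_TO_AA == "*"]

#' The 61 sense codons in fixed order
#' @keywords internal
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' Amino acid of each sense codon (one-letter)
#' @keywords internal
SENSE_AA <- CODON_TO_AA[SENSE_CODONS]

#' Synonymous family sizes, keyed by one-letter amino acid
#' @keywords internal
FAMILY_SIZE <- table(SENSE_AA)

# One- to three-letter amino-acid names, for report readability.
AA_THREE <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val"
)

# The eight amino acids whose tRNAs carry the A34 -> inosine modification by
# ADAT (tRNA-dependent adenosine deaminase), which broadens wobble decoding.
ADAT_AMINO_ACIDS <- c("A", "R", "I", "L", "P", "S", "T", "V")

#' Reverse complement of a codon/anticodon string
#'
#' Vectorised over 3-mers; used to pair codons with their Watson-Crick
#' cognate anticodons.
#'
#' @param x character vector of 3-letter DNA strings over A/C/G/T
#' @return character vector of reverse complements
#' @export
revcomp_codon <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(b) paste(comp[rev(b)], collapse = ""), "")
}
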