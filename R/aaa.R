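#' @useDynLib cppscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict coef
NULL

# The 20 canonical one-letter amino-acid codes, the only residue alphabet
# accepted anywhere in the package.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PEPTIDE_LABELS <- c("CPP", "NON_CPP", "UNKNOWN")
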