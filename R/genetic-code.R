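# Standard genetic code (translation table 1) and the 12-class amino-acid
# characteristic alphabet used as the top level of the reference hierarchy.

# codon -> one-letter residue, "*" for stop (from Biostrings, table 1)
.GENETIC_CODE <- Biostrings::GENETIC_CODE

# residue (or "*") -> characteristic class label. Residues are grouped by
# side-chain charge/polarity, then by volume; C, G, H, M and P are sole
# members of their classes; "L" is reserved for the stop symbol.
.AA_CHAR <- c(
  K = "A", R = "A",
  H = "B",
  D = "C", E = "C",
  S = "D", T = "D",
  N = "E", Q = "E",
  C = "F",
  G = "G",
  P = "H",
  M = "I",
  A = "J", I = "J", L = "J", V = "J",
  F = "K", W = "K", Y = "K",
  "*" = "L"
)

#' Translate a codon under the standard genetic code
#'
#' @param codon Character vector of 3-nt DNA codons (alphabet ACGT,
#'   case-insensitive).
#' @return Character vector of one-letter amino-acid codes; `"*"` for a stop
#'   codon.
#' @examples
#' translate_codon(c("AAA", "ATG", "TAA"))
#' @export
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  bad <- is.na(codon) | nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         " (must be 3 nt over ACGT)")
  }
  unname(.GENETIC_CODE[codon])
}

#' Characteristic class of an amino acid
#'
#' Maps each of the 20 standard residues, or the stop symbol `"*"`, to one of
#' the 12 characteristic class labels `A`-`L` (`L` = stop).
#'
#' @param residue Character vector of one-letter residue codes or `"*"`.
#' @return Character vector of class labels.
#' @examples
#' char_of(c("K", "H", "*"))
#' @export
char_of <- function(residue) {
  residue <- toupper(as.character(residue))
  out <- .AA_CHAR[residue]
  if (anyNA(out)) {
    stop("unknown residue(s): ",
         paste(unique(residue[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Translate a 3-codon DNA 9-mer to its amino-acid trimer
#'
#' @param ninemer Character vector of 9-nt DNA strings.
#' @return Character vector of amino-acid trimers; a stop codon is rendered
#'   as `"*"`.
#' @examples
#' ninemer_to_trimer("GATGATCAT")  # "DDH"
#' @export
ninemer_to_trimer <- function(ninemer) {
  ninemer <- toupper(as.character(ninemer))
  bad <- is.na(ninemer) | nchar(ninemer) != 9L | grepl("[^ACGT]", ninemer)
  if (any(bad)) {
    stop("invalid 9-mer(s): ", paste(unique(ninemer[bad]), collapse = ", "),
         " (must be 9 nt over ACGT)")
  }
  paste0(.GENETIC_CODE[substring(ninemer, 1L, 3L)],
         .GENETIC_CODE[substring(ninemer, 4L, 6L)],
         .GENETIC_CODE[substring(ninemer, 7L, 9L)])
}

#' Characteristic trimer of an amino-acid trimer
#'
#' @param trimer Character vector of length-3 residue strings (stop symbol
#'   `"*"` allowed, as arising from query-side translation).
#' @return Character vector of 3-letter characteristic class strings.
#' @examples
#' trimer_to_char_trimer("DDH")  # "CCB"
#' @export
trimer_to_char_trimer <- function(trimer) {
  trimer <- toupper(as.character(trimer))
  bad <- is.na(trimer) | nchar(trimer) != 3L
  if (any(bad)) stop("trimer(s) must be 3 residues")
  out <- paste0(.AA_CHAR[substring(trimer, 1L, 1L)],
                .AA_CHAR[substring(trimer, 2L, 2L)],
                .AA_CHAR[substring(trimer, 3L, 3L)])
  if (any(grepl("NA", out, fixed = TRUE))) {
    stop("unknown residue(s) in trimer(s): ",
         paste(unique(trimer[grepl("NA", out, fixed = TRUE)]), collapse = ", "))
  }
  out
}

# internal: fast, non-validating vectorised versions for scanning loops
.trans9 <- function(ninemer) {
  paste0(.GENETIC_CODE[substring(ninemer, 1L, 3L)],
         .GENETIC_CODE[substring(ninemer, 4L, 6L)],
         .GENETIC_CODE[substring(ninemer, 7L, 9L)])
}

# all codons of a residue family (incl. stop family for "*")
.codons_of <- local({
  fam <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  function(residue) fam[[residue]]
})

# reverse complement of plain character DNA
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
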