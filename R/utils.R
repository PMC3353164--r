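#' @useDynLib vamir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Normalize nucleotide sequences to the DNA alphabet
#'
#' Uppercases and converts U to T, so RNA-style input (e.g. miRBase mature
#' sequences) and DNA-style input can be compared directly.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,T,N\}.
#' @export
norm_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of character sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Percentage with fixed rounding
#'
#' The 2-decimal percentage convention used throughout the report tables
#' (e.g. 18,902,700 / 19,692,474 -> 95.99).
#'
#' @param count numerator.
#' @param total denominator.
#' @param digits decimal places (default 2).
#' @return numeric percentage.
#' @export
pct <- function(count, total, digits = 2) {
  round(100 * count / total, digits)
}

#' Extract the miRNA family label from a mature miRNA id
#'
#' Family is the "miR" stem plus its number; letter suffixes, member dashes
#' and species prefixes are ignored (e.g. "vvi-miR156a" -> "miR156").
#'
#' @param id character vector of miRNA ids.
#' @return character vector of family labels (NA when no family is parseable).
#' @export
mir_family <- function(id) {
  m <- regmatches(id, regexpr("[Mm][Ii][Rr]-?[0-9]+", id))
  out <- rep(NA_character_, length(id))
  hit <- regexpr("[Mm][Ii][Rr]-?[0-9]+", id) > 0
  out[hit] <- paste0("miR", sub("^[Mm][Ii][Rr]-?", "", m))
  out
}

#' Extract the species prefix from a miRBase-style id
#'
#' @param id character vector like "ath-miR156a".
#' @return character vector of species codes (NA when absent).
#' @export
mir_species <- function(id) {
  out <- rep(NA_character_, length(id))
  hit <- grepl("^[A-Za-z]{2,4}-", id)
  out[hit] <- sub("-.*$", "", id[hit])
  out
}

# Hamming distance between equal-length strings (vectorised over b).
hamming <- function(a, b) {
  stopifnot(all(nchar(b) == nchar(a)))
  va <- strsplit(a, "")[[1]]
  vapply(strsplit(b, ""), function(vb) sum(vb != va), integer(1))
}

# Do two bases pair in the duplex sense (Watson-Crick or G:U wobble)?
# `a` is a miRNA base, `b` the target base, both 5'->3' DNA alphabet.
base_pairs <- function(a, b) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
  ifelse(wc, "match", ifelse(gu, "GU", "mismatch"))
}
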