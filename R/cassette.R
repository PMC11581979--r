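#' @importFrom Biostrings DNAString DNAStringSet AAStringSet translate
#'   readAAStringSet readDNAStringSet writeXStringSet GENETIC_CODE
#'   IUPAC_CODE_MAP consensusMatrix
NULL

# Approximate E. coli K-12 codon-usage fractions (per amino acid); the
# "max_usage" codon policy only depends on the per-amino-acid argmax.
ECOLI_CODON_USAGE <- c(
  TTT = 0.57, TTC = 0.43, TTA = 0.13, TTG = 0.13, CTT = 0.10, CTC = 0.10,
  CTA = 0.04, CTG = 0.50, ATT = 0.51, ATC = 0.42, ATA = 0.07, ATG = 1.00,
  GTT = 0.26, GTC = 0.22, GTA = 0.15, GTG = 0.37, TCT = 0.15, TCC = 0.15,
  TCA = 0.12, TCG = 0.15, AGT = 0.15, AGC = 0.28, CCT = 0.16, CCC = 0.12,
  CCA = 0.19, CCG = 0.53, ACT = 0.17, ACC = 0.44, ACA = 0.13, ACG = 0.26,
  GCT = 0.16, GCC = 0.27, GCA = 0.21, GCG = 0.36, TAT = 0.57, TAC = 0.43,
  CAT = 0.57, CAC = 0.43, CAA = 0.35, CAG = 0.65, AAT = 0.45, AAC = 0.55,
  AAA = 0.77, AAG = 0.23, GAT = 0.63, GAC = 0.37, GAA = 0.69, GAG = 0.31,
  TGT = 0.45, TGC = 0.55, TGG = 1.00, CGT = 0.38, CGC = 0.40, CGA = 0.06,
  CGG = 0.10, AGA = 0.04, AGG = 0.02, GGT = 0.34, GGC = 0.40, GGA = 0.11,
  GGG = 0.15)

#' Translate a DNA string (standard code)
#'
#' @param dna nucleotide sequence whose length is divisible by 3.
#' @return amino-acid sequence; stop codons become "*".
#' @export
translateDna <- function(dna) {
  if (nchar(dna) %% 3L != 0L) stop("DNA length must be divisible by 3")
  if (nchar(dna) == 0L) return("")
  codons <- substring(dna, seq(1L, nchar(dna), 3L), seq(3L, nchar(dna), 3L))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Preferred codon for an amino acid under a usage policy
#'
#' @param aa one-letter amino acid.
#' @param policy only "max_usage" is built in: the most-used codon in the
#'   bundled E. coli K-12 usage table.
#' @return a plain codon (character of length 3).
#' @export
preferredCodon <- function(aa, policy = "max_usage") {
  if (!identical(policy, "max_usage")) stop("unknown codon policy: ", policy)
  codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
  if (!length(codons)) stop("no codon encodes ", aa)
  codons[which.max(ECOLI_CODON_USAGE[codons])]
}

#' Reverse-translate a protein with preferred codons
#'
#' @param protein amino-acid sequence.
#' @param policy codon policy, see \code{\link{preferredCodon}}.
#' @return DNA sequence of length 3 x nchar(protein).
#' @export
reverseTranslate <- function(protein, policy = "max_usage") {
  aas <- strsplit(protein, "")[[1]]
  paste(vapply(aas, preferredCodon, "", policy = policy), collapse = "")
}

#' Construct an expression cassette
#'
#' @param dna cassette nucleotide sequence (5'->3').
#' @param orfStart,orfEnd 0-based half-open ORF interval. When omitted the
#'   whole cassette is taken as the ORF.
#' @return an \linkS4class{ExpressionCassette}.
#' @export
expressionCassette <- function(dna, orfStart = 0L, orfEnd = nchar(dna)) {
  dna <- toupper(dna)
  orf <- substr(dna, orfStart + 1L, orfEnd)
  new("ExpressionCassette", dna = dna, orfStart = as.integer(orfStart),
      orfEnd = as.integer(orfEnd), protein = translateDna(orf))
}

#' 0-based half-open nucleotide interval of a codon
#'
#' @param cassette an \linkS4class{ExpressionCassette}.
#' @param position 1-based amino-acid position on the encoded protein.
#' @return integer c(start, end) on the cassette.
#' @export
codonInterval <- function(cassette, position) {
  if (position < 1L || position > nchar(cassette@protein))
    stop("amino-acid position outside the ORF")
  s <- cassette@orfStart + 3L * (position - 1L)
  c(start = s, end = s + 3L)
}
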