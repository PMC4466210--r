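# Vertebrate mitochondrial genetic code (NCBI translation table 2).
# Differs from the standard code at four codons: AGA/AGG are stop,
# ATA is Met, TGA is Trp.
.mito_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

.mito_stop_codons <- names(.mito_code)[.mito_code == "*"]

#' Translate an in-frame DNA sequence under the vertebrate mitochondrial code
#'
#' Stops are rendered as `"*"`. Codons containing characters outside
#' `A`/`C`/`G`/`T` translate to `"X"`.
#'
#' @param cds Character scalar, DNA sequence whose length is a multiple of 3.
#' @return Character scalar amino-acid sequence.
#' @export
#' @examples
#' translate_mito("ATGTGAAGA") # "MW*" -- TGA is Trp, AGA is stop
translate_mito <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("coding sequence length (", n, ") is not a multiple of 3")
  }
  if (n == 0L) {
    return("")
  }
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(.mito_code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Classify the protein-level effect of a single-base substitution
#'
#' The affected codon is translated before and after the substitution under
#' the vertebrate mitochondrial genetic code. A substitution is `"synonymous"`
#' when the amino acid is unchanged, `"nonsense"` when the variant codon is a
#' stop, `"missense"` otherwise, and `"unknown"` when either codon contains a
#' non-ACGT character. Coordinates are 1-based with base 1 the first base of
#' codon 1.
#'
#' @param cds In-frame DNA string (length a multiple of 3).
#' @param position 1-based position of the substituted base within `cds`.
#' @param alt_base The variant base, one of `A`, `C`, `G`, `T`.
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`, `"unknown"`.
#' @export
#' @examples
#' classify_codon_effect("CTACTA", 3, "C")  # synonymous (Leu -> Leu)
#' classify_codon_effect("AGCAAA", 3, "A")  # nonsense (AGC -> AGA, mito stop)
classify_codon_effect <- function(cds, position, alt_base) {
  cds <- toupper(cds)
  alt_base <- toupper(alt_base)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("coding sequence length (", n, ") is not a multiple of 3")
  }
  if (position < 1L || position > n) {
    stop("position ", position, " outside coding sequence of length ", n)
  }
  if (!alt_base %in% c("A", "C", "G", "T")) {
    stop("alt_base must be one of A, C, G, T; got '", alt_base, "'")
  }
  ref_base <- substr(cds, position, position)
  if (identical(ref_base, alt_base)) {
    stop("not a substitution: reference base at position ", position,
         " already is '", alt_base, "'")
  }
  codon_start <- position - ((position - 1L) %% 3L)
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, position - codon_start + 1L,
         position - codon_start + 1L) <- alt_base
  ref_aa <- .mito_code[ref_codon]
  alt_aa <- .mito_code[alt_codon]
  if (is.na(ref_aa) || is.na(alt_aa)) {
    return("unknown")
  }
  if (identical(unname(ref_aa), unname(alt_aa))) {
    return("synonymous")
  }
  if (alt_aa == "*") {
    return("nonsense")
  }
  "missense"
}
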