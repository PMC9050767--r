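# Standard genetic code tables shared by all modules.
#
# Sequences are handled in the DNA alphabet internally; user-facing tables
# spell codons with U (RNA alphabet), the convention of most codon usage
# literature.  `to_rna()` / `to_dna()` convert between the two.

#' Convert codon spelling between DNA and RNA alphabets
#'
#' @param x character vector of codons or sequences.
#' @return `x` with T replaced by U (`to_rna`) or U by T (`to_dna`).
#' @export
to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname to_rna
#' @export
to_dna <- function(x) chartr("Uu", "Tt", x)

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODON <- "ATG"
BASES <- c("A", "C", "G", "T")

# 64-row codon table in fixed alphabetical codon order (deterministic layout).
CODON_TABLE <- local({
  code <- Biostrings::GENETIC_CODE
  codon <- sort(names(code))
  aa <- unname(code[codon])
  aa3map <- c(Biostrings::AMINO_ACID_CODE, "*" = "Ter")
  fam <- table(aa)
  data.frame(
    codon = codon,
    aa = aa,
    aa3 = unname(aa3map[aa]),
    family_size = as.integer(fam[aa]),
    base1 = substr(codon, 1, 1),
    base2 = substr(codon, 2, 2),
    base3 = substr(codon, 3, 3),
    stringsAsFactors = FALSE
  )
})

SENSE_CODONS <- CODON_TABLE$codon[CODON_TABLE$aa != "*"]          # 61
# Met, Trp and stops carry no synonymous choice; the remaining 59 codons
# span the space in which codon usage bias is measured.
CUB_CODONS <- setdiff(SENSE_CODONS, c(START_CODON, "TGG"))        # 59

# Synonymous families of the 18 degenerate amino acids (plus the stop
# "family", reported alongside but never entering the bias indices).
AA_FAMILIES <- local({
  s <- CODON_TABLE[CODON_TABLE$aa != "*", ]
  split(s$codon, s$aa)
})
FAMILY_SIZE <- vapply(AA_FAMILIES, length, integer(1))
DEGENERATE_AA <- names(FAMILY_SIZE)[FAMILY_SIZE >= 2]             # 18
DEGENERATE_CODONS <- unlist(AA_FAMILIES[DEGENERATE_AA], use.names = FALSE)

# Degeneracy classes used by Wright's ENC: 9 twofold, 1 threefold (Ile),
# 5 fourfold, 3 sixfold (Leu, Ser, Arg) amino acids.
DEGENERACY_CLASS <- FAMILY_SIZE[DEGENERATE_AA]

# The eight fully fourfold-degenerate codon boxes used by the PR2 plot:
# prefixes whose four completions all encode the same amino acid (includes
# the fourfold boxes of the sixfold amino acids Leu, Ser, Arg).
FOURFOLD_BOX_PREFIX <- local({
  pre <- unique(substr(SENSE_CODONS, 1, 2))
  keep <- vapply(pre, function(p) {
    cods <- paste0(p, BASES)
    all(cods %in% SENSE_CODONS) &&
      length(unique(CODON_TABLE$aa[match(cods, CODON_TABLE$codon)])) == 1L
  }, logical(1))
  pre[keep]
})
FOURFOLD_BOX_CODONS <- as.vector(outer(FOURFOLD_BOX_PREFIX, BASES, paste0))

# Kyte-Doolittle hydropathy values, one per amino acid.
KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)
AROMATIC_AA <- c("F", "Y", "W")

#' The standard genetic code as a codon table
#'
#' Returns the 64-row codon table used throughout the package: codon (DNA
#' spelling), one- and three-letter amino acid (stops as `*` / `Ter`),
#' synonymous family size and the three codon position bases.
#'
#' @return A data frame with one row per codon in alphabetical order.
#' @examples
#' head(genetic_code())
#' @export
genetic_code <- function() CODON_TABLE

#' Label codons by their third base
#'
#' Codons are split into AT-ending and GC-ending groups, the colour coding
#' conventionally used on correspondence-analysis biplots of codon usage.
#'
#' @param codons character vector of codons (DNA or RNA spelling); defaults
#'   to the 59 codons informative for codon usage bias.
#' @return named character vector, values `"AT-ending"` or `"GC-ending"`.
#' @examples
#' codon_ending_labels(c("GCU", "GCC"))
#' @export
codon_ending_labels <- function(codons = to_rna(CUB_CODONS)) {
  third <- substr(to_dna(codons), 3, 3)
  stopifnot(all(third %in% BASES))
  stats::setNames(ifelse(third %in% c("A", "T"), "AT-ending", "GC-ending"),
                  codons)
}

# internal: amino acids of a codon vector
codon_aa <- function(codons) {
  CODON_TABLE$aa[match(codons, CODON_TABLE$codon)]
}
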