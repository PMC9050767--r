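# Codon-pair context (adjacent codon pairs within genes) and amino-acid
# usage summaries.

#' Adjacent codon-pair counts
#'
#' Counts ordered pairs of adjacent codons (P1 followed by P2) within each
#' gene; pairs never span gene boundaries.  Start and stop codons are
#' included, so AUG- and stop-adjacent pairs appear in the tally.
#'
#' @param seqs named character vector of QC-passed CDS.
#' @return 64 x 64 integer matrix (rows P1, columns P2, DNA spelling), with
#'   attribute `total_pairs` = sum over genes of (codons per gene - 1).
#' @examples
#' codon_pair_counts(c(g = "ATGAAAAAATAA"))["AAA", "AAA"]
#' @export
codon_pair_counts <- function(seqs) {
  m <- matrix(0L, 64L, 64L,
              dimnames = list(CODON_TABLE$codon, CODON_TABLE$codon))
  for (seq in seqs) {
    cods <- codon_split(seq)
    if (length(cods) < 2L) next
    p1 <- match(cods[-length(cods)], CODON_TABLE$codon)
    p2 <- match(cods[-1L], CODON_TABLE$codon)
    tab <- table(factor(p1, levels = 1:64), factor(p2, levels = 1:64))
    m <- m + as.integer(tab)
  }
  attr(m, "total_pairs") <- sum(m)
  m
}

#' Top-ranked codon pairs
#'
#' Ranks codon pairs by descending count (ties broken alphabetically on
#' (P1, P2)) and flags pairs made of two preferred codons and pairs of two
#' identical codons.  The preferred flag is only meaningful for codons of
#' degenerate amino acids; pairs involving start/stop codons are never
#' flagged preferred.
#'
#' @param pair_matrix matrix from [codon_pair_counts()].
#' @param preferred preferred codon set, e.g. [preferred_codons()] output
#'   (RNA or DNA spelling).
#' @param n number of top pairs to return (default 20).
#' @return data frame: `codon1`, `codon2` (RNA spelling), `count`, `rank`,
#'   `both_preferred`, `identical`; attribute `summary` tallies the two
#'   flags.
#' @export
top_pairs <- function(pair_matrix, preferred = NULL, n = 20) {
  idx <- which(pair_matrix > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty codon-pair matrix")
  df <- data.frame(
    codon1 = rownames(pair_matrix)[idx[, 1L]],
    codon2 = colnames(pair_matrix)[idx[, 2L]],
    count = pair_matrix[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$count, df$codon1, df$codon2), ]
  df <- utils::head(df, n)
  df$rank <- seq_len(nrow(df))
  pref <- if (is.null(preferred)) character(0) else to_dna(preferred)
  df$both_preferred <- df$codon1 %in% pref & df$codon2 %in% pref
  df$identical <- df$codon1 == df$codon2
  df$codon1 <- to_rna(df$codon1)
  df$codon2 <- to_rna(df$codon2)
  rownames(df) <- NULL
  attr(df, "summary") <- c(both_preferred = sum(df$both_preferred),
                           identical = sum(df$identical))
  df
}

#' Amino-acid usage frequencies
#'
#' Residue frequencies over the translated proteins of a gene set (stops
#' excluded), with a roll-up by degeneracy class (1-, 2-, 3-, 4- and
#' 6-fold amino acids).
#'
#' @param seqs named character vector of QC-passed CDS.
#' @param include_start whether the initial Met residues are counted
#'   (default `TRUE`: the translated protein includes its start).
#' @return list with `aa` (per amino acid: `aa`, `aa3`, `degeneracy`,
#'   `count`, `freq`) and `by_class` (per degeneracy class aggregate
#'   frequency); frequencies each sum to 1.
#' @export
aa_frequencies <- function(seqs, include_start = TRUE) {
  aa <- unlist(lapply(names(seqs), function(id) {
    r <- strsplit(translate_cds(seqs[[id]], id), "")[[1L]]
    if (!include_start && length(r) && r[1L] == "M") r <- r[-1L]
    r
  }), use.names = FALSE)
  lev <- sort(names(AA_FAMILIES))
  counts <- table(factor(aa, levels = lev))
  total <- sum(counts)
  aa3map <- stats::setNames(CODON_TABLE$aa3, CODON_TABLE$aa)
  per_aa <- data.frame(
    aa = lev,
    aa3 = unname(aa3map[lev]),
    degeneracy = unname(FAMILY_SIZE[lev]),
    count = as.integer(counts),
    freq = as.numeric(counts) / total,
    stringsAsFactors = FALSE
  )
  by_class <- stats::aggregate(cbind(count, freq) ~ degeneracy, per_aa, sum)
  list(aa = per_aa, by_class = by_class)
}
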