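# Nucleotide composition: overall and positional base content, positional
# GC, and silent-site base propensities.
#
# Two third-position conventions are exposed deliberately:
#   * plain positional fractions (positional_base_fractions), used by the
#     PR2 diagnostics, where the four bases sum to one; and
#   * silent-site propensities A3s/T3s/G3s/C3s (silent_site_composition),
#     where each base is normalised by the number of synonymous codons whose
#     family offers that base at the third position.  Under the second
#     convention the four values need not sum to 100; it is the convention
#     behind the classical composition tables produced by codon usage
#     software, and the one reported in `gene_composition()`.

#' Per-position base fractions of a codon count vector
#'
#' @param counts named count vector over the 64 codons
#'   (see [count_codons()]).
#' @return 3 x 4 matrix (codon positions x bases A,C,G,T); each row sums
#'   to 1.
#' @export
positional_base_fractions <- function(counts) {
  counts <- as_codon_counts(counts)
  total <- sum(counts)
  if (total == 0) stop("empty codon count vector")
  m <- rbind(
    pos1 = tapply(counts, CODON_TABLE$base1, sum),
    pos2 = tapply(counts, CODON_TABLE$base2, sum),
    pos3 = tapply(counts, CODON_TABLE$base3, sum)
  )[, BASES]
  m / total
}

# internal: coerce/validate a 64-codon count vector in canonical order
as_codon_counts <- function(counts) {
  stopifnot(!is.null(names(counts)))
  out <- stats::setNames(numeric(64L), CODON_TABLE$codon)
  idx <- match(names(counts), CODON_TABLE$codon)
  if (anyNA(idx)) stop("unknown codon name: ",
                       names(counts)[which(is.na(idx))[1L]])
  out[idx] <- counts
  out
}

#' Positional GC content and derived quantities
#'
#' @inheritParams positional_base_fractions
#' @return named numeric vector (percent scale): `GC1`, `GC2`, `GC3`,
#'   `GC12` (= mean of GC1 and GC2), `GC`, `AT`, `AT3` (= 100 - GC3),
#'   `AT2` (= 100 - GC2).
#' @examples
#' gc_by_position(count_codons("ATGGCGGCGTAA"))
#' @export
gc_by_position <- function(counts) {
  f <- positional_base_fractions(counts)
  gc <- 100 * rowSums(f[, c("C", "G")])
  out <- c(GC1 = unname(gc["pos1"]), GC2 = unname(gc["pos2"]),
           GC3 = unname(gc["pos3"]))
  out["GC12"] <- (out[["GC1"]] + out[["GC2"]]) / 2
  out["GC"] <- mean(gc)
  out["AT"] <- 100 - out[["GC"]]
  out["AT3"] <- 100 - out[["GC3"]]
  out["AT2"] <- 100 - out[["GC2"]]
  out
}

# internal: per-family third-base availability (does family f offer base b
# at a synonymous third position?), rows = degenerate families.
FAMILY_THIRD_AVAIL <- local({
  m <- t(vapply(AA_FAMILIES[DEGENERATE_AA],
                function(cods) BASES %in% substr(cods, 3, 3),
                logical(4L)))
  colnames(m) <- BASES
  m
})

#' Silent-site base propensities (A3s, T3s, G3s, C3s)
#'
#' For each base b, the fraction of synonymous codon occurrences that end
#' in b among those whose family offers b at the third position.  Only
#' codons of degenerate amino acids contribute; the four values do not in
#' general sum to 100.
#'
#' @inheritParams positional_base_fractions
#' @return named numeric vector `A3s`, `T3s`, `G3s`, `C3s` (percent scale);
#'   `NaN` where no degenerate codon could carry the base.
#' @export
silent_site_composition <- function(counts) {
  counts <- as_codon_counts(counts)
  deg <- CODON_TABLE$codon %in% DEGENERATE_CODONS
  aa <- CODON_TABLE$aa
  num <- den <- stats::setNames(numeric(4L), BASES)
  for (b in BASES) {
    num[b] <- sum(counts[deg & CODON_TABLE$base3 == b])
    avail_fams <- rownames(FAMILY_THIRD_AVAIL)[FAMILY_THIRD_AVAIL[, b]]
    den[b] <- sum(counts[deg & aa %in% avail_fams])
  }
  out <- 100 * num / den
  stats::setNames(out[c("A", "T", "G", "C")],
                  c("A3s", "T3s", "G3s", "C3s"))
}

#' Full composition record for one gene
#'
#' @param seq a single CDS (DNA alphabet).
#' @param include_start,include_stop whether the initial ATG / terminal stop
#'   codon enter the tallies (default `FALSE`, matching the index
#'   computations).
#' @return one-row data frame: overall A/T/G/C/GC/AT percentages,
#'   positional GC (GC1, GC2, GC3, GC12, AT3, AT2), silent-site
#'   propensities (A3s, T3s, G3s, C3s), `L_sym` (synonymous codons) and
#'   `L_aa` (translated codons).
#' @export
gene_composition <- function(seq, include_start = FALSE,
                             include_stop = FALSE) {
  counts <- count_codons(seq, include_start = include_start,
                         include_stop = include_stop)
  composition_from_counts(counts)
}

# internal: composition record from a codon count vector
composition_from_counts <- function(counts) {
  counts <- as_codon_counts(counts)
  f <- positional_base_fractions(counts)
  base_pct <- 100 * colMeans(f)  # overall base content of the coding region
  gc <- gc_by_position(counts)
  s3 <- silent_site_composition(counts)
  sense <- CODON_TABLE$aa != "*"
  data.frame(
    A = base_pct[["A"]], T = base_pct[["T"]],
    G = base_pct[["G"]], C = base_pct[["C"]],
    GC = gc[["GC"]], AT = gc[["AT"]],
    GC1 = gc[["GC1"]], GC2 = gc[["GC2"]], GC3 = gc[["GC3"]],
    GC12 = gc[["GC12"]], AT3 = gc[["AT3"]], AT2 = gc[["AT2"]],
    A3s = s3[["A3s"]], T3s = s3[["T3s"]],
    G3s = s3[["G3s"]], C3s = s3[["C3s"]],
    L_sym = sum(counts[CODON_TABLE$codon %in% DEGENERATE_CODONS]),
    L_aa = sum(counts[sense]),
    row.names = NULL
  )
}

#' Per-gene composition table for a set of CDS
#'
#' @param seqs named character vector of QC-passed CDS.
#' @inheritParams gene_composition
#' @return data frame with one row per gene (`gene_id` first column).
#' @export
composition_table <- function(seqs, include_start = FALSE,
                              include_stop = FALSE) {
  recs <- lapply(seqs, gene_composition, include_start = include_start,
                 include_stop = include_stop)
  cbind(data.frame(gene_id = names(seqs), stringsAsFactors = FALSE),
        do.call(rbind, recs))
}

#' Dataset-level composition summary
#'
#' Column means over genes (the single-value-per-species convention of
#' comparative composition tables), together with the composition of the
#' pooled codon counts.
#'
#' @param comp per-gene composition table from [composition_table()].
#' @param seqs optional: the sequences themselves, to add the pooled-count
#'   composition row.
#' @return data frame with rows `mean` and (if `seqs` given) `pooled`.
#' @export
composition_summary <- function(comp, seqs = NULL) {
  stopifnot(nrow(comp) >= 1L)
  num <- comp[, setdiff(names(comp), "gene_id"), drop = FALSE]
  out <- as.data.frame(t(colMeans(num)))
  rownames(out) <- "mean"
  if (!is.null(seqs)) {
    pooled <- composition_from_counts(colSums(codon_count_matrix(seqs)))
    rownames(pooled) <- "pooled"
    out <- rbind(out, pooled)
  }
  out
}
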