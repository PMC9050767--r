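# Reading CDS FASTA files, quality control, codon decomposition and
# translation.  QC mirrors the filtering conventions of comparative codon
# usage studies: a kept CDS starts with ATG, ends with a stop codon, has no
# ambiguous base, no internal in-frame stop, a length divisible by three and
# at least `min_length_nt` nucleotides.

QC_REASONS <- c("too_short", "bad_start", "bad_stop",
                "ambiguous_base", "not_multiple_of_3")

#' Read coding sequences from a FASTA file
#'
#' Sequences are uppercased and U is normalised to T so that all downstream
#' computation works in the DNA alphabet.  Duplicated record identifiers are
#' made unique with a warning (both records are kept).
#'
#' @param path path to a (multi-)FASTA file of CDS.
#' @return named character vector of sequences; zero-length (with a warning)
#'   for an empty file.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    warning("no FASTA records found in ", path)
    return(stats::setNames(character(0), character(0)))
  }
  seqs <- toupper(chartr("U", "T", as.character(recs)))
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids)) {
    warning("duplicated record identifiers in ", path,
            "; suffixing to make them unique")
    ids <- make.unique(ids, sep = "_dup")
  }
  stats::setNames(unname(seqs), ids)
}

# internal: split one sequence into codons (length must be divisible by 3)
codon_split <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# internal: first failing QC rule for one sequence, or NA if it passes.
qc_reason <- function(seq, min_length_nt) {
  n <- nchar(seq)
  if (n < min_length_nt) return("too_short")
  if (n >= 3L && substr(seq, 1L, 3L) != START_CODON) return("bad_start")
  if (n < 3L || !(substr(seq, n - 2L, n) %in% STOP_CODONS)) return("bad_stop")
  if (n %% 3L == 0L) {
    cods <- codon_split(seq)
    if (any(cods[-length(cods)] %in% STOP_CODONS)) return("bad_stop")
  }
  if (grepl("[^ACGT]", seq)) return("ambiguous_base")
  if (n %% 3L != 0L) return("not_multiple_of_3")
  NA_character_
}

#' Quality-filter coding sequences
#'
#' Applies, in order: minimum length, ATG start, valid stop (terminal stop
#' present and no internal in-frame stop), no ambiguous base, length
#' divisible by three.  Each rejected record is assigned the first rule it
#' fails.  Filtering is idempotent: re-filtering the kept set rejects
#' nothing.
#'
#' @param seqs named character vector from [read_cds_fasta()].
#' @param min_length_nt minimum CDS length in nucleotides (default 100;
#'   shorter sequences are excluded to limit sampling error in the indices).
#' @return list with `sequences` (kept, named character) and `report`
#'   (data frame: `gene_id`, `status`, `reason`).
#' @examples
#' qc_filter(c(g1 = "ATGAAATAA"), min_length_nt = 9)
#' @export
qc_filter <- function(seqs, min_length_nt = 100) {
  stopifnot(is.character(seqs))
  if (is.null(names(seqs)) && length(seqs))
    names(seqs) <- paste0("seq_", seq_along(seqs))
  reason <- vapply(seqs, qc_reason, character(1), min_length_nt = min_length_nt)
  keep <- is.na(reason)
  report <- data.frame(
    gene_id = names(seqs),
    status = ifelse(keep, "kept", "rejected"),
    reason = ifelse(keep, "", reason),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(sequences = seqs[keep], report = report),
            class = "cub_qc")
}

#' @export
print.cub_qc <- function(x, ...) {
  n <- nrow(x$report)
  cat("CDS quality control: ", sum(x$report$status == "kept"), " kept / ",
      n, " input records\n", sep = "")
  rej <- x$report$reason[x$report$status == "rejected"]
  if (length(rej)) print(table(factor(rej, levels = QC_REASONS)))
  invisible(x)
}

#' Count codon occurrences in a coding sequence
#'
#' @param seq a single CDS (character scalar, DNA alphabet, length divisible
#'   by 3).
#' @param include_start count the initial ATG (default `FALSE`).
#' @param include_stop count the terminal stop codon (default `FALSE`).
#' @return named integer vector over the 64 codons (alphabetical order).
#' @examples
#' count_codons("ATGAAAAAATAA")
#' @export
count_codons <- function(seq, include_start = FALSE, include_stop = FALSE) {
  stopifnot(length(seq) == 1L, nchar(seq) %% 3L == 0L)
  cods <- codon_split(seq)
  if (!include_stop && length(cods) && cods[length(cods)] %in% STOP_CODONS)
    cods <- cods[-length(cods)]
  if (!include_start && length(cods) && cods[1L] == START_CODON)
    cods <- cods[-1L]
  tab <- table(factor(cods, levels = CODON_TABLE$codon))
  stats::setNames(as.integer(tab), CODON_TABLE$codon)
}

#' Codon count matrix for a set of genes
#'
#' @param seqs named character vector of CDS.
#' @inheritParams count_codons
#' @return integer matrix, genes x 64 codons.
#' @export
codon_count_matrix <- function(seqs, include_start = FALSE,
                               include_stop = FALSE) {
  m <- t(vapply(seqs, count_codons, integer(64L),
                include_start = include_start, include_stop = include_stop))
  colnames(m) <- CODON_TABLE$codon
  m
}

#' Translate a coding sequence
#'
#' Standard genetic code; the terminal stop codon is dropped.  An internal
#' in-frame stop is an error naming the gene and codon position (such
#' sequences are rejected by [qc_filter()] beforehand in the normal flow).
#'
#' @param seq a single CDS (DNA alphabet, length divisible by 3).
#' @param id gene identifier used in error messages.
#' @return amino-acid string, one residue per sense codon.
#' @examples
#' translate_cds("ATGAAATAA")
#' @export
translate_cds <- function(seq, id = "sequence") {
  stopifnot(length(seq) == 1L, nchar(seq) %% 3L == 0L)
  cods <- codon_split(seq)
  if (length(cods) && cods[length(cods)] %in% STOP_CODONS)
    cods <- cods[-length(cods)]
  aa <- codon_aa(cods)
  if (anyNA(aa))
    stop("unrecognised codon in ", id, " at codon position ",
         which(is.na(aa))[1L])
  if (any(aa == "*"))
    stop("internal stop codon in ", id, " at codon position ",
         which(aa == "*")[1L])
  paste(aa, collapse = "")
}

#' Write sequences to FASTA
#'
#' Deterministic single-line-per-sequence FASTA writer (byte-identical
#' output for identical input).
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
  invisible(path)
}
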