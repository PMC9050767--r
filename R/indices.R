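# The classical codon usage bias index suite.
#
# RSCU_ij = x_ij / ((1/n_i) * sum_j x_ij): observed count of codon j of
# amino acid i over the count expected under uniform synonymous usage.
# Classification thresholds follow the standard convention: RSCU > 1
# high-frequency, < 1 low-frequency, > 1.6 overrepresented, < 0.6
# underrepresented (strict inequalities); the preferred codon of an amino
# acid is its maximum-RSCU codon.
#
# ENC is Wright's estimator: per synonymous family with n >= 2 counted
# codons, F_hat = (n * sum(p^2) - 1) / (n - 1); F_hat is averaged within
# each degeneracy class and ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, capped at
# 61.  If only the threefold class (Ile) is missing its mean is imputed as
# (F2 + F4)/2; with two or more classes missing ENC is NA.
#
# CAI is the geometric mean of relative adaptiveness weights
# w_ij = RSCU_ij / max_j RSCU_ij computed from a reference count vector,
# taken over the gene's synonymous codon occurrences (Met/Trp/stops
# excluded).  CBI = (N_opt - N_ran)/(N_tot - N_ran) with N_ran the uniform
# expectation of optimal-codon use; Fop = N_opt / N_tot.

#' Relative synonymous codon usage
#'
#' Computes RSCU for every codon, including the non-informative Met and Trp
#' rows and the stop ("Ter") family, and classifies codons against the
#' 1 / 1.6 / 0.6 thresholds.  Within each family with at least one observed
#' codon the RSCU values sum to the family size; families with zero total
#' count get `NA` (undefined), not 0.
#'
#' @param counts named count vector over codons (e.g. [count_codons()] with
#'   `include_stop = TRUE` if the stop rows are wanted), or a genes x codons
#'   matrix whose column sums are used.
#' @return data frame with one row per codon: `codon` (RNA spelling), `aa`,
#'   `aa3`, `family_size`, `count`, `rscu`, logical flags `high`, `low`,
#'   `overrepresented`, `underrepresented`, `preferred` and `informative`
#'   (degenerate amino acid).
#' @examples
#' rscu(count_codons("ATGGCTGCTGCTGCCTAA"))
#' @export
rscu <- function(counts) {
  if (is.matrix(counts)) counts <- colSums(counts)
  counts <- as_codon_counts(counts)
  tab <- CODON_TABLE
  fam_total <- tapply(counts, tab$aa, sum)[tab$aa]
  val <- ifelse(fam_total > 0,
                counts / (fam_total / tab$family_size), NA_real_)
  out <- data.frame(
    codon = to_rna(tab$codon),
    aa = tab$aa,
    aa3 = tab$aa3,
    family_size = tab$family_size,
    count = unname(counts),
    rscu = unname(val),
    stringsAsFactors = FALSE
  )
  classify_codons(out)
}

#' Classify codons from their RSCU values
#'
#' Adds/refreshes the threshold flags and the per-amino-acid preferred
#' codon (maximum RSCU among degenerate amino acids; ties broken towards
#' the alphabetically first codon with a warning).
#'
#' @param rscu_table data frame with at least `codon`, `aa`, `family_size`
#'   and `rscu` columns (as produced by [rscu()]).
#' @return the table with `high`, `low`, `overrepresented`,
#'   `underrepresented`, `preferred` and `informative` columns set.
#' @export
classify_codons <- function(rscu_table) {
  x <- rscu_table
  x$high <- !is.na(x$rscu) & x$rscu > 1
  x$low <- !is.na(x$rscu) & x$rscu < 1
  x$overrepresented <- !is.na(x$rscu) & x$rscu > 1.6
  x$underrepresented <- !is.na(x$rscu) & x$rscu < 0.6
  x$informative <- x$aa %in% DEGENERATE_AA
  x$preferred <- FALSE
  for (a in intersect(unique(x$aa), DEGENERATE_AA)) {
    i <- which(x$aa == a & !is.na(x$rscu))
    if (!length(i)) next
    top <- i[x$rscu[i] == max(x$rscu[i])]
    if (length(top) > 1L) {
      top <- top[order(x$codon[top])]
      warning("preferred-codon tie for ", a,
              "; keeping ", x$codon[top[1L]])
    }
    x$preferred[top[1L]] <- TRUE
  }
  x
}

#' Preferred codons of an RSCU table
#'
#' @param rscu_table output of [rscu()] (or any table with `aa`, `codon`
#'   and `preferred` columns).
#' @return named character vector, amino acid -> preferred codon (RNA
#'   spelling), over the 18 degenerate amino acids.
#' @export
preferred_codons <- function(rscu_table) {
  p <- rscu_table[rscu_table$preferred, ]
  stats::setNames(p$codon, p$aa)[sort(p$aa)]
}

# internal: Wright F-hat per degeneracy class; returns named numeric
# c("2","3","4","6") with NA where the class could not be estimated.
enc_class_F <- function(counts) {
  counts <- as_codon_counts(counts)
  Fhat <- rep(NA_real_, length(DEGENERATE_AA))
  names(Fhat) <- DEGENERATE_AA
  for (a in DEGENERATE_AA) {
    x <- counts[AA_FAMILIES[[a]]]
    n <- sum(x)
    if (n < 2) next
    p <- x / n
    Fhat[a] <- (n * sum(p^2) - 1) / (n - 1)
  }
  vapply(c("2", "3", "4", "6"), function(k) {
    v <- Fhat[DEGENERACY_CLASS == as.integer(k)]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Effective number of codons (Wright's ENC)
#'
#' @param counts named codon count vector for one gene (start/stop
#'   excluded, as produced by [count_codons()] defaults).
#' @return ENC in \[20, 61\], or `NA` when the gene is too short to
#'   estimate the class averages (see file header for the imputation rule).
#' @examples
#' enc(count_codons(paste0("ATG", strrep("AAAGAATTTCTTCTCCTACTGGGT", 20),
#'                         "TAA")))
#' @export
enc <- function(counts) {
  Fbar <- enc_class_F(counts)
  miss <- names(Fbar)[is.na(Fbar)]
  if (identical(miss, "3"))
    Fbar[["3"]] <- mean(c(Fbar[["2"]], Fbar[["4"]]))
  else if (length(miss))
    return(NA_real_)
  if (any(Fbar <= 0)) return(NA_real_)
  val <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] +
    5 / Fbar[["4"]] + 3 / Fbar[["6"]]
  min(val, 61)
}

#' Relative adaptiveness weights from a reference count vector
#'
#' w_ij = RSCU_ij / RSCU_i,max within each synonymous family.  Codons
#' unobserved in the reference get a small floor (default 0.01) so that
#' downstream geometric means stay finite; families entirely absent from
#' the reference get uninformative weights of 1.
#'
#' @param ref_counts named codon count vector of the reference set.
#' @param floor weight assigned to reference-absent codons.
#' @return named numeric vector of weights over the 59 codons informative
#'   for codon usage bias (DNA spelling).
#' @export
reference_weights <- function(ref_counts, floor = 0.01) {
  counts <- as_codon_counts(ref_counts)
  w <- stats::setNames(rep(1, length(CUB_CODONS)), CUB_CODONS)
  for (a in DEGENERATE_AA) {
    fam <- AA_FAMILIES[[a]]
    x <- counts[fam]
    if (sum(x) == 0) next           # uninformative family: keep w = 1
    w[fam] <- pmax(x / max(x), floor)
  }
  w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness weights over the gene's
#' synonymous codon occurrences (Met, Trp and stops excluded).
#'
#' @param counts named codon count vector for the gene.
#' @param weights weights from [reference_weights()] (or user-supplied,
#'   named by DNA codon with the family maxima equal to 1).
#' @return CAI in (0, 1\]; `NA` for a gene without synonymous codons.
#' @export
cai <- function(counts, weights) {
  counts <- as_codon_counts(counts)[CUB_CODONS]
  w <- weights[CUB_CODONS]
  if (anyNA(w)) stop("weights must cover all 59 synonymous codons")
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  exp(sum(counts * log(w)) / n)
}

#' Optimal codon set
#'
#' Default: the maximum-RSCU (preferred) codon of each degenerate amino
#' acid, from a dataset-level RSCU table; a user-supplied set overrides it.
#'
#' @param rscu_table dataset-level RSCU table from [rscu()].
#' @param user optional named character vector amino acid -> codon (DNA or
#'   RNA spelling) taking precedence over the computed set.
#' @return named character vector amino acid -> codon (DNA spelling), one
#'   per degenerate amino acid.
#' @export
optimal_codon_set <- function(rscu_table, user = NULL) {
  if (!is.null(user)) {
    user <- stats::setNames(to_dna(user), names(user))
    bad <- !(codon_aa(user) == names(user))
    if (any(bad %in% TRUE) || anyNA(codon_aa(user)))
      stop("user optimal set contains codons not encoding the named amino acid")
    return(user[sort(names(user))])
  }
  stats::setNames(to_dna(preferred_codons(rscu_table)),
                  names(preferred_codons(rscu_table)))
}

# internal: optimal / total / uniform-expected counts over degenerate
# families for one gene
opt_counts <- function(counts, optimal) {
  counts <- as_codon_counts(counts)
  n_opt <- sum(counts[optimal])
  n_tot <- 0
  n_ran <- 0
  for (a in DEGENERATE_AA) {
    fam_n <- sum(counts[AA_FAMILIES[[a]]])
    n_tot <- n_tot + fam_n
    n_ran <- n_ran + fam_n / FAMILY_SIZE[[a]]
  }
  c(opt = n_opt, tot = n_tot, ran = n_ran)
}

#' Codon bias index
#'
#' CBI = (N_opt - N_ran) / (N_tot - N_ran), where N_ran is the number of
#' optimal codons expected under uniform synonymous usage.  0 means usage
#' indistinguishable from uniform, 1 means exclusive use of optimal codons;
#' values below 0 indicate avoidance of the optimal set.
#'
#' @inheritParams cai
#' @param optimal optimal codon set from [optimal_codon_set()] (DNA
#'   spelling, one codon per degenerate amino acid).
#' @return CBI value, `NA` for a gene without synonymous codons.
#' @export
cbi <- function(counts, optimal) {
  n <- opt_counts(counts, optimal)
  if (n[["tot"]] == 0 || n[["tot"]] == n[["ran"]]) return(NA_real_)
  (n[["opt"]] - n[["ran"]]) / (n[["tot"]] - n[["ran"]])
}

#' Frequency of optimal codons
#'
#' @inheritParams cbi
#' @return Fop = N_opt / N_tot in \[0, 1\].
#' @export
fop <- function(counts, optimal) {
  n <- opt_counts(counts, optimal)
  if (n[["tot"]] == 0) return(NA_real_)
  n[["opt"]] / n[["tot"]]
}

#' GRAVY: grand average of hydropathy
#'
#' Mean Kyte-Doolittle hydropathy over the residues of a protein; positive
#' values indicate hydrophobic proteins.
#'
#' @param protein amino-acid string(s), one-letter code.
#' @return numeric vector of GRAVY values.
#' @examples
#' gravy("IR")  # mean of +4.5 (Ile) and -4.5 (Arg)
#' @export
gravy <- function(protein) {
  vapply(protein, function(p) {
    aa <- strsplit(p, "")[[1L]]
    v <- KYTE_DOOLITTLE[aa]
    if (anyNA(v)) stop("unknown residue in protein sequence")
    mean(v)
  }, numeric(1), USE.NAMES = !is.null(names(protein)))
}

#' Aromaticity
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp).
#'
#' @inheritParams gravy
#' @return numeric vector in \[0, 1\].
#' @examples
#' aromo("FAYA")
#' @export
aromo <- function(protein) {
  vapply(protein, function(p) {
    aa <- strsplit(p, "")[[1L]]
    mean(aa %in% AROMATIC_AA)
  }, numeric(1), USE.NAMES = !is.null(names(protein)))
}

#' Per-gene codon usage bias index table
#'
#' Computes ENC, CAI, CBI, Fop, GRAVY and AROMO for every gene, together
#' with its full composition record.  By default the CAI reference weights
#' are self-referential (pooled counts of the dataset itself); with
#' `cai_ref = "top_enc"` the reference is the lowest-ENC (most biased)
#' quantile of genes, a proxy for highly expressed genes when no external
#' reference is available.
#'
#' @param seqs named character vector of QC-passed CDS.
#' @param cai_ref `"self"`, `"top_enc"`, or a named codon count vector to
#'   use as the reference set.
#' @param top_enc_q quantile of lowest-ENC genes used when
#'   `cai_ref = "top_enc"` (default 0.1).
#' @param optimal optional user optimal codon set (see
#'   [optimal_codon_set()]).
#' @param weight_floor floor for reference-absent codon weights.
#' @return data frame, one row per gene: `gene_id`, `ENC`, `CAI`, `CBI`,
#'   `Fop`, `GRAVY`, `AROMO` and the composition columns.
#' @export
gene_indices <- function(seqs, cai_ref = c("self", "top_enc"),
                         top_enc_q = 0.1, optimal = NULL,
                         weight_floor = 0.01) {
  stopifnot(length(seqs) >= 1L)
  m <- codon_count_matrix(seqs)
  enc_v <- apply(m, 1L, enc)
  if (is.numeric(cai_ref)) {
    ref_counts <- cai_ref
  } else {
    cai_ref <- match.arg(cai_ref)
    ref_counts <- if (cai_ref == "self") colSums(m) else {
      ord <- order(enc_v)
      top <- ord[seq_len(max(1L, ceiling(top_enc_q * length(seqs))))]
      colSums(m[top, , drop = FALSE])
    }
  }
  w <- reference_weights(ref_counts, floor = weight_floor)
  opt <- optimal_codon_set(rscu(colSums(m)), user = optimal)
  prot <- vapply(names(seqs), function(id) translate_cds(seqs[[id]], id),
                 character(1))
  comp <- composition_table(seqs)
  data.frame(
    gene_id = names(seqs),
    ENC = unname(enc_v),
    CAI = apply(m, 1L, cai, weights = w),
    CBI = apply(m, 1L, cbi, optimal = opt),
    Fop = apply(m, 1L, fop, optimal = opt),
    GRAVY = unname(gravy(prot)),
    AROMO = unname(aromo(prot)),
    comp[, setdiff(names(comp), "gene_id")],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
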