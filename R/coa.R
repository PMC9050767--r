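# Correspondence analysis of the gene x codon RSCU matrix.
#
# Standard CA: divide the non-negative table by its grand total, form the
# matrix of standardized residuals S = D_r^{-1/2} (P - r c') D_c^{-1/2}
# from the row and column masses, and take its singular value
# decomposition.  Axis i carries inertia share lambda_i / sum(lambda) with
# lambda_i the squared singular values; rows and columns are reported in
# principal (symmetric) coordinates.  Axis signs are fixed by making the
# first nonzero column (codon) coordinate on each axis positive, so
# repeated runs are reproducible.

#' Gene x codon RSCU matrix
#'
#' Builds the genes x 59 codons matrix of per-gene RSCU values that
#' correspondence analysis operates on.  Families absent from a gene have
#' undefined RSCU; these entries are imputed as 0 (with a message giving
#' the number of imputations) to keep the fixed 59-column layout.
#'
#' @param seqs named character vector of QC-passed CDS.
#' @return numeric matrix, genes x 59 codons (RNA spelling columns).
#' @export
rscu_matrix <- function(seqs) {
  m <- codon_count_matrix(seqs)[, CUB_CODONS, drop = FALSE]
  aa <- codon_aa(CUB_CODONS)
  fs <- CODON_TABLE$family_size[match(CUB_CODONS, CODON_TABLE$codon)]
  out <- matrix(0, nrow = length(seqs), ncol = length(CUB_CODONS),
                dimnames = list(names(seqs), to_rna(CUB_CODONS)))
  n_imputed <- 0L
  for (i in seq_along(seqs)) {
    fam_tot <- tapply(m[i, ], aa, sum)[aa]
    val <- ifelse(fam_tot > 0, m[i, ] / (fam_tot / fs), NA_real_)
    n_imputed <- n_imputed + sum(is.na(val))
    out[i, ] <- ifelse(is.na(val), 0, val)
  }
  if (n_imputed > 0L)
    message(n_imputed, " undefined RSCU entries (absent families) imputed as 0")
  out
}

#' Correspondence analysis of a non-negative matrix
#'
#' @param mat non-negative matrix (typically [rscu_matrix()] output: genes
#'   as rows, the 59 informative codons as columns).  All-zero rows or
#'   columns are dropped with a warning.
#' @param n_axes number of axes to report coordinates for (default 4; the
#'   inertia shares of all axes are always returned).
#' @return object of class `"cub_coa"`: `inertia` (percent share per
#'   axis), `total_inertia`, `row_coords`, `col_coords` (principal
#'   coordinates, first `n_axes` axes), `col_labels` (AT-/GC-ending when
#'   the columns are codons), `n_axes_total`.
#' @export
coa_fit <- function(mat, n_axes = 4) {
  stopifnot(is.matrix(mat), all(mat >= 0), nrow(mat) >= 3L)
  zr <- rowSums(mat) == 0
  zc <- colSums(mat) == 0
  if (any(zr)) warning("dropping ", sum(zr), " all-zero row(s)")
  if (any(zc)) warning("dropping ", sum(zc), " all-zero column(s)")
  mat <- mat[!zr, !zc, drop = FALSE]
  P <- mat / sum(mat)
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  k_max <- min(nrow(mat), ncol(mat)) - 1L
  d <- sv$d[seq_len(k_max)]
  lambda <- d^2
  total <- sum(lambda)
  inertia <- if (total > 0) 100 * lambda / total else rep(0, k_max)
  k <- min(n_axes, k_max)
  Frow <- diag(1 / sqrt(r)) %*% sv$u[, seq_len(k), drop = FALSE] %*%
    diag(d[seq_len(k)], nrow = k)
  Gcol <- diag(1 / sqrt(cc)) %*% sv$v[, seq_len(k), drop = FALSE] %*%
    diag(d[seq_len(k)], nrow = k)
  # sign convention: first nonzero column coordinate on each axis positive
  for (j in seq_len(k)) {
    nz <- which(abs(Gcol[, j]) > 1e-12)
    if (length(nz) && Gcol[nz[1L], j] < 0) {
      Gcol[, j] <- -Gcol[, j]
      Frow[, j] <- -Frow[, j]
    }
  }
  dimnames(Frow) <- list(rownames(mat), paste0("Axis", seq_len(k)))
  dimnames(Gcol) <- list(colnames(mat), paste0("Axis", seq_len(k)))
  labels <- tryCatch(codon_ending_labels(colnames(mat)),
                     error = function(e) NULL)
  structure(list(
    inertia = stats::setNames(inertia, paste0("Axis", seq_len(k_max))),
    total_inertia = total,
    row_coords = Frow,
    col_coords = Gcol,
    col_labels = labels,
    n_axes_total = k_max
  ), class = "cub_coa")
}

#' @export
print.cub_coa <- function(x, ...) {
  cat("Correspondence analysis: ", nrow(x$row_coords), " rows x ",
      nrow(x$col_coords), " columns\n", sep = "")
  cat("Total inertia:", format(x$total_inertia, digits = 4), "\n")
  k <- min(4L, x$n_axes_total)
  cat("Inertia shares (%):",
      paste(sprintf("%s %.2f", names(x$inertia)[seq_len(k)],
                    x$inertia[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}
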