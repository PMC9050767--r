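# Evolutionary-force diagnostics: Wright's expected ENC curve, the PR2
# (parity rule 2) plot at fourfold-degenerate third positions, the
# neutrality regression of GC12 on GC3, and index correlation tables.

#' Wright's expected ENC under mutation pressure alone
#'
#' ENC expected for a gene whose only source of bias is its third-position
#' GC content s: `2 + s + 29 / (s^2 + (1 - s)^2)`.
#'
#' @param s GC3 as a fraction in \[0, 1\] (vectorised).
#' @return expected ENC value(s).
#' @examples
#' enc_expected(0.5)  # 60.5
#' @export
enc_expected <- function(s) {
  stopifnot(all(s >= 0 & s <= 1, na.rm = TRUE))
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' ENC-GC3 plot table
#'
#' Per-gene observed ENC, expected ENC at the gene's GC3, and a
#' classification of the gene as on/above/below the expected curve.  Genes
#' within `tol` ENC units of the curve are called "on" (the tolerance for
#' "near the line" is not standardised; 1 ENC unit is the default here).
#'
#' @param indices per-gene index table from [gene_indices()] (needs `ENC`
#'   and `GC3` columns; `GC3` on the percent scale).
#' @param tol half-width of the "on the curve" band, in ENC units.
#' @return data frame: `gene_id`, `GC3`, `ENC`, `ENC_expected`, `deviation`
#'   (`ENC - ENC_expected`), `position` (factor above/on/below), plus a
#'   `counts` attribute with the summary tally.
#' @export
enc_plot_table <- function(indices, tol = 1) {
  stopifnot(all(c("gene_id", "ENC", "GC3") %in% names(indices)))
  expd <- enc_expected(indices$GC3 / 100)
  dev <- indices$ENC - expd
  pos <- factor(ifelse(is.na(dev), NA,
                       ifelse(abs(dev) <= tol, "on",
                              ifelse(dev > 0, "above", "below"))),
                levels = c("above", "on", "below"))
  out <- data.frame(gene_id = indices$gene_id, GC3 = indices$GC3,
                    ENC = indices$ENC, ENC_expected = expd,
                    deviation = dev, position = pos,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(pos)
  out
}

#' PR2 (parity rule 2) coordinates for one gene
#'
#' AT bias A3/(A3 + T3) and GC bias G3/(G3 + C3) computed over the third
#' positions of the eight fully fourfold-degenerate codon boxes (GCN, CGN,
#' GGN, CTN, CCN, TCN, ACN, GTN).  (0.5, 0.5) indicates parity, i.e. no
#' strand asymmetry between mutation and selection at silent sites.
#'
#' @param counts named codon count vector for the gene.
#' @return named numeric vector `at_bias`, `gc_bias`; a coordinate is `NA`
#'   (invalid) when its denominator is zero.
#' @examples
#' pr2_point(count_codons("ATGGCTGCAGCTGCATAA"))
#' @export
pr2_point <- function(counts) {
  counts <- as_codon_counts(counts)[FOURFOLD_BOX_CODONS]
  third <- substr(FOURFOLD_BOX_CODONS, 3, 3)
  n <- vapply(BASES, function(b) sum(counts[third == b]), numeric(1))
  at <- if (n[["A"]] + n[["T"]] > 0) n[["A"]] / (n[["A"]] + n[["T"]]) else NA_real_
  gc <- if (n[["G"]] + n[["C"]] > 0) n[["G"]] / (n[["G"]] + n[["C"]]) else NA_real_
  c(at_bias = at, gc_bias = gc)
}

#' PR2 table for a set of genes
#'
#' @param seqs named character vector of QC-passed CDS.
#' @return data frame: `gene_id`, `at_bias`, `gc_bias`, `valid` (both
#'   coordinates defined).
#' @export
pr2_table <- function(seqs) {
  m <- codon_count_matrix(seqs)
  pts <- t(apply(m, 1L, pr2_point))
  data.frame(gene_id = names(seqs),
             at_bias = pts[, "at_bias"], gc_bias = pts[, "gc_bias"],
             valid = !is.na(pts[, "at_bias"]) & !is.na(pts[, "gc_bias"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Neutrality regression of GC12 on GC3
#'
#' Ordinary least squares of per-gene GC12 on GC3 across genes, with the
#' Pearson correlation and its two-tailed t-test p-value.  A slope near 1
#' indicates that directional mutation pressure dominates codon usage; a
#' slope near 0 indicates selection and other compositional constraints
#' (the selection share is conventionally read as 1 - slope).
#'
#' @param gc3,gc12 numeric vectors (same scale, typically percent), or a
#'   data frame with `GC3` and `GC12` columns passed as `gc3`.
#' @return object of class `"neutrality_fit"`: slope, intercept, `r`, `p`,
#'   `n`, the fitted `lm`, and the (GC3, GC12) pairs.
#' @export
neutrality_fit <- function(gc3, gc12 = NULL) {
  if (is.data.frame(gc3)) {
    stopifnot(all(c("GC3", "GC12") %in% names(gc3)))
    gc12 <- gc3$GC12
    gc3 <- gc3$GC3
  }
  ok <- stats::complete.cases(gc3, gc12)
  gc3 <- gc3[ok]; gc12 <- gc12[ok]
  if (length(gc3) < 3L) stop("need at least 3 genes with valid GC12 and GC3")
  fit <- stats::lm(gc12 ~ gc3)
  if (stats::sd(gc3) == 0 || stats::sd(gc12) == 0) {
    # degenerate spread: correlation undefined, reported as 0 / p = 1
    ct <- list(estimate = c(cor = 0), p.value = 1)
  } else {
    ct <- suppressWarnings(stats::cor.test(gc3, gc12))
  }
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r = unname(ct$estimate),
    p = ct$p.value,
    n = length(gc3),
    mutation_share = unname(stats::coef(fit)[2L]),
    selection_share = 1 - unname(stats::coef(fit)[2L]),
    lm = fit,
    data = data.frame(GC3 = gc3, GC12 = gc12)
  ), class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, digits = 4, ...) {
  cat("Neutrality regression (GC12 ~ GC3), n =", x$n, "genes\n")
  cat("  slope     :", format(x$slope, digits = digits),
      " (mutation share ", format(100 * x$mutation_share, digits = digits),
      "%, selection share ", format(100 * x$selection_share, digits = digits),
      "%)\n", sep = "")
  cat("  intercept :", format(x$intercept, digits = digits), "\n")
  cat("  Pearson r :", format(x$r, digits = digits),
      ", p =", format.pval(x$p, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.neutrality_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Pairwise correlation table of index columns
#'
#' Correlations (Pearson by default, Spearman optionally) between columns
#' of the per-gene index table, with two-tailed p-values and, as a
#' convenience, Benjamini-Hochberg adjusted p-values (the raw p-values are
#' the primary output; no correction is applied to them).
#'
#' @param indices per-gene index table ([gene_indices()]).
#' @param vars character vector of column names to correlate; defaults to
#'   the classical set.
#' @param method `"pearson"` or `"spearman"`.
#' @return data frame: `var1`, `var2`, `r`, `p`, `p_bh`, `n` (one row per
#'   unordered pair), with an `r_matrix` attribute holding the symmetric
#'   correlation matrix.
#' @export
correlate_indices <- function(indices,
                              vars = c("ENC", "CAI", "CBI", "Fop", "GRAVY",
                                       "AROMO", "GC", "GC1", "GC2", "GC3",
                                       "GC12", "AT3", "T3s", "A3s"),
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vars <- intersect(vars, names(indices))
  stopifnot(length(vars) >= 2L)
  pairs <- utils::combn(vars, 2L)
  rows <- apply(pairs, 2L, function(v) {
    x <- indices[[v[1L]]]; y <- indices[[v[2L]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L) return(data.frame(var1 = v[1L], var2 = v[2L],
                                        r = NA_real_, p = NA_real_,
                                        n = sum(ok)))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method))
    data.frame(var1 = v[1L], var2 = v[2L],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("var1", "var2", "r", "p", "p_bh", "n")]
  rmat <- diag(1, length(vars))
  dimnames(rmat) <- list(vars, vars)
  for (i in seq_len(nrow(out))) {
    rmat[out$var1[i], out$var2[i]] <- rmat[out$var2[i], out$var1[i]] <- out$r[i]
  }
  attr(out, "r_matrix") <- rmat
  out
}
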