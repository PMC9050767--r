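# Single-species analysis object: every table of a comparative codon usage
# study for one gene set, bundled with print/summary/plot methods.

#' Full codon usage bias profile of one gene set
#'
#' Runs the complete single-species analysis: QC, per-gene composition and
#' dataset summary, pooled RSCU with codon classification, the per-gene
#' index suite (ENC, CAI, CBI, Fop, GRAVY, AROMO), ENC-GC3 and PR2 plot
#' tables, the neutrality regression, index correlations, correspondence
#' analysis of the gene x codon RSCU matrix, top codon pairs and amino-acid
#' usage.
#'
#' @param x a FASTA path, a named character vector of CDS, or a
#'   `Biostrings::DNAStringSet`.
#' @param label species/sample label used in printing.
#' @param min_length_nt QC length threshold (see [qc_filter()]).
#' @param cai_ref,top_enc_q,optimal see [gene_indices()].
#' @param enc_tol "on the expected ENC curve" tolerance, in ENC units.
#' @param cor_method correlation method for [correlate_indices()].
#' @param n_top_pairs number of top codon pairs to keep.
#' @return object of class `"cub_profile"`; its components (`qc`,
#'   `composition`, `composition_summary`, `rscu`, `indices`, `enc_plot`,
#'   `pr2`, `neutrality`, `correlations`, `coa`, `top_pairs`, `aa_usage`)
#'   are the tables described above.
#' @examples
#' sim <- simulate_cds(sim_config(n_genes = 30, seed = 7))
#' prof <- codon_usage_profile(sim$sequences, label = "synthetic")
#' prof
#' @export
codon_usage_profile <- function(x, label = "sample", min_length_nt = 100,
                                cai_ref = "self", top_enc_q = 0.1,
                                optimal = NULL, enc_tol = 1,
                                cor_method = "pearson",
                                n_top_pairs = 20) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- read_cds_fasta(x)
  if (inherits(x, "XStringSet"))
    x <- stats::setNames(as.character(x), names(x))
  stopifnot(is.character(x))
  qc <- qc_filter(x, min_length_nt = min_length_nt)
  seqs <- qc$sequences
  if (length(seqs) == 0L)
    stop("no sequences passed quality control for ", label)
  comp <- composition_table(seqs)
  idx <- gene_indices(seqs, cai_ref = cai_ref, top_enc_q = top_enc_q,
                      optimal = optimal)
  pooled <- colSums(codon_count_matrix(seqs, include_stop = TRUE))
  rscu_tab <- rscu(pooled)
  coa <- if (length(seqs) >= 3L)
    suppressMessages(coa_fit(rscu_matrix(seqs))) else NULL
  neut <- if (length(seqs) >= 3L) neutrality_fit(idx) else NULL
  cors <- if (length(seqs) >= 3L)
    correlate_indices(idx, method = cor_method) else NULL
  pairs <- top_pairs(codon_pair_counts(seqs),
                     preferred = preferred_codons(rscu_tab),
                     n = n_top_pairs)
  structure(list(
    label = label,
    qc = qc,
    sequences = seqs,
    composition = comp,
    composition_summary = composition_summary(comp, seqs),
    rscu = rscu_tab,
    indices = idx,
    enc_plot = enc_plot_table(idx, tol = enc_tol),
    pr2 = pr2_table(seqs),
    neutrality = neut,
    correlations = cors,
    coa = coa,
    top_pairs = pairs,
    aa_usage = aa_frequencies(seqs),
    call = match.call()
  ), class = "cub_profile")
}

#' @export
print.cub_profile <- function(x, ...) {
  cat("Codon usage bias profile: ", x$label, "\n", sep = "")
  cat("  genes analysed : ", length(x$sequences), " (",
      sum(x$qc$report$status == "rejected"), " rejected at QC)\n", sep = "")
  s <- summary(x)
  cat(sprintf("  mean ENC %.2f | CAI %.3f | CBI %.3f | Fop %.3f\n",
              s$ENC, s$CAI, s$CBI, s$Fop))
  cat(sprintf("  mean GC%% %.2f (GC3 %.2f) | GRAVY %.3f | AROMO %.3f\n",
              s$GC, s$GC3, s$GRAVY, s$AROMO))
  if (!is.null(x$neutrality))
    cat(sprintf("  neutrality slope %.3f (r = %.3f, p = %.3g)\n",
                x$neutrality$slope, x$neutrality$r, x$neutrality$p))
  if (!is.null(x$coa))
    cat(sprintf("  CoA axis 1: %.2f%%, axis 2: %.2f%% of inertia\n",
                x$coa$inertia[1L], x$coa$inertia[2L]))
  invisible(x)
}

#' Species-level summary of a codon usage profile
#'
#' One row of dataset means, the analogue of a per-species row of a
#' comparative index table.
#'
#' @param object a `cub_profile`.
#' @param ... unused.
#' @return one-row data frame of mean ENC, CBI, CAI, GRAVY, AROMO, Fop and
#'   the mean composition columns.
#' @export
summary.cub_profile <- function(object, ...) {
  idx <- object$indices
  num <- idx[, setdiff(names(idx), "gene_id"), drop = FALSE]
  out <- as.data.frame(t(colMeans(num, na.rm = TRUE)))
  cbind(data.frame(label = object$label, n_genes = nrow(idx),
                   stringsAsFactors = FALSE), out)
}

#' Diagnostic plots for a codon usage profile
#'
#' Base-graphics renderings of the standard diagnostics: `"enc"` (ENC vs
#' GC3 with Wright's expected curve), `"pr2"` (PR2 plot with centre
#' lines), `"neutrality"` (GC12 vs GC3 with the regression line), `"coa"`
#' (codon coordinates on the first two axes, coloured by AT-/GC-ending)
#' and `"aa"` (amino-acid usage bar chart).
#'
#' @param x a `cub_profile`.
#' @param type which diagnostic to draw.
#' @param ... passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.cub_profile <- function(x, type = c("enc", "pr2", "neutrality",
                                         "coa", "aa"), ...) {
  type <- match.arg(type)
  if (type == "enc") {
    with(x$enc_plot, graphics::plot(
      GC3, ENC, xlab = "GC3 (%)", ylab = "ENC", xlim = c(0, 100),
      ylim = c(20, 62), main = paste("ENC-GC3 plot:", x$label),
      pch = 20, col = "grey30", ...))
    s <- seq(0, 1, length.out = 200)
    graphics::lines(100 * s, enc_expected(s), lwd = 2)
  } else if (type == "pr2") {
    ok <- x$pr2[x$pr2$valid, ]
    graphics::plot(ok$gc_bias, ok$at_bias, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "G3/(G3+C3)", ylab = "A3/(A3+T3)",
                   main = paste("PR2 plot:", x$label), pch = 20,
                   col = "grey30", ...)
    graphics::abline(h = 0.5, v = 0.5, lty = 2)
  } else if (type == "neutrality") {
    stopifnot(!is.null(x$neutrality))
    d <- x$neutrality$data
    graphics::plot(d$GC3, d$GC12, xlab = "GC3 (%)", ylab = "GC12 (%)",
                   main = paste("Neutrality plot:", x$label), pch = 20,
                   col = "grey30", ...)
    graphics::abline(x$neutrality$intercept, x$neutrality$slope, lwd = 2)
  } else if (type == "coa") {
    stopifnot(!is.null(x$coa))
    g <- x$coa$col_coords
    col <- ifelse(x$coa$col_labels == "GC-ending", "black", "brown")
    graphics::plot(g[, 1L], g[, 2L], col = col, pch = 20,
                   xlab = sprintf("Axis 1 (%.2f%%)", x$coa$inertia[1L]),
                   ylab = sprintf("Axis 2 (%.2f%%)", x$coa$inertia[2L]),
                   main = paste("CoA codon coordinates:", x$label), ...)
    graphics::abline(h = 0, v = 0, lty = 3)
    graphics::text(g[, 1L], g[, 2L], rownames(g), cex = 0.5, pos = 3,
                   col = col)
  } else {
    u <- x$aa_usage$aa
    graphics::barplot(stats::setNames(u$freq, u$aa3), las = 2,
                      ylab = "frequency",
                      main = paste("Amino-acid usage:", x$label), ...)
  }
  invisible(x)
}
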