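# Multi-species orchestration: run the full analysis per species, write
# all tables as TSV, and compare preferred-codon usage across species.
#
# All tables are written deterministically (fixed column order, fixed
# number formatting, no timestamps), so identical inputs and configuration
# give byte-identical output files.

TSV_SCHEMA <- "# codonbias table v1"

# internal: deterministic TSV writer with a schema version header line
write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(TSV_SCHEMA, con, sep = "\n")
  writeLines(paste(names(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cells <- vapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 10, trim = TRUE,
                                  scientific = FALSE)
      else as.character(col)
    }, character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a TSV written by the pipeline
#'
#' @param path file path.
#' @return data frame.
#' @export
read_cub_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# internal: all per-species tables of a profile as data frames
profile_tables <- function(prof) {
  cs <- prof$composition_summary
  cs <- cbind(data.frame(statistic = rownames(cs)), cs)
  rownames(cs) <- NULL
  neut <- if (is.null(prof$neutrality)) NULL else
    data.frame(slope = prof$neutrality$slope,
               intercept = prof$neutrality$intercept,
               r = prof$neutrality$r, p = prof$neutrality$p,
               n = prof$neutrality$n,
               selection_share = prof$neutrality$selection_share)
  coa <- prof$coa
  list(
    qc_report = prof$qc$report,
    composition_genes = prof$composition,
    composition_summary = cs,
    gene_indices = prof$indices,
    rscu = prof$rscu,
    enc_plot = prof$enc_plot,
    pr2 = prof$pr2,
    neutrality = neut,
    correlations = prof$correlations,
    coa_inertia = if (is.null(coa)) NULL else
      data.frame(axis = names(coa$inertia), inertia_pct = coa$inertia,
                 row.names = NULL),
    coa_genes = if (is.null(coa)) NULL else
      cbind(data.frame(gene_id = rownames(coa$row_coords)),
            as.data.frame(coa$row_coords, row.names = FALSE)),
    coa_codons = if (is.null(coa)) NULL else
      cbind(data.frame(codon = rownames(coa$col_coords),
                       ending = unname(coa$col_labels)),
            as.data.frame(coa$col_coords, row.names = FALSE)),
    top_pairs = prof$top_pairs,
    aa_usage = prof$aa_usage$aa,
    aa_usage_by_class = prof$aa_usage$by_class
  )
}

#' Run the full multi-species codon usage pipeline
#'
#' Analyses each input gene set with [codon_usage_profile()], writes every
#' table to `<out_dir>/<label>/<table>.tsv`, and writes the cross-species
#' preferred-codon agreement table to `<out_dir>/preferred_codon_agreement.tsv`.
#'
#' @param inputs named list/vector: one FASTA path or named character
#'   vector of CDS per species; names are the species labels (must be
#'   unique).
#' @param out_dir output directory (created if needed).
#' @param ... passed to [codon_usage_profile()] (QC threshold, CAI
#'   reference, tolerances, ...).
#' @return invisibly, a list with `profiles` (per species) and `agreement`
#'   (see [preferred_codon_agreement()]).
#' @export
run_pipeline <- function(inputs, out_dir, ...) {
  stopifnot(length(inputs) >= 1L, !is.null(names(inputs)),
            !anyDuplicated(names(inputs)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- lapply(names(inputs), function(lab) {
    codon_usage_profile(inputs[[lab]], label = lab, ...)
  })
  names(profiles) <- names(inputs)
  for (lab in names(profiles)) {
    d <- file.path(out_dir, lab)
    dir.create(d, showWarnings = FALSE)
    tabs <- profile_tables(profiles[[lab]])
    for (nm in names(tabs)) {
      if (!is.null(tabs[[nm]])) write_tsv(tabs[[nm]],
                                          file.path(d, paste0(nm, ".tsv")))
    }
  }
  agreement <- if (length(profiles) >= 2L)
    preferred_codon_agreement(lapply(profiles, `[[`, "rscu")) else NULL
  if (!is.null(agreement))
    write_tsv(agreement$pairs,
              file.path(out_dir, "preferred_codon_agreement.tsv"))
  invisible(list(profiles = profiles, agreement = agreement))
}

#' Preferred-codon agreement between species
#'
#' Counts, for every pair of species, how many of the 18 degenerate amino
#' acids have the same preferred (maximum-RSCU) codon, and lists the
#' disagreeing amino acids.
#'
#' @param rscu_tables named list of [rscu()] tables (or any tables accepted
#'   by [preferred_codons()]), one per species.
#' @return list with `pairs` (data frame: `species1`, `species2`,
#'   `n_shared`, `n_compared`, `differing_aa`) and `preferred` (amino acid
#'   x species matrix of preferred codons).
#' @export
preferred_codon_agreement <- function(rscu_tables) {
  stopifnot(length(rscu_tables) >= 2L, !is.null(names(rscu_tables)))
  prefs <- lapply(rscu_tables, preferred_codons)
  aas <- sort(Reduce(union, lapply(prefs, names)))
  mat <- vapply(prefs, function(p) p[aas], character(length(aas)))
  rownames(mat) <- aas
  combos <- utils::combn(names(rscu_tables), 2L)
  pairs <- apply(combos, 2L, function(v) {
    a <- mat[, v[1L]]; b <- mat[, v[2L]]
    ok <- !is.na(a) & !is.na(b)
    same <- ok & a == b
    data.frame(species1 = v[1L], species2 = v[2L],
               n_shared = sum(same), n_compared = sum(ok),
               differing_aa = paste(rownames(mat)[ok & a != b],
                                    collapse = ","),
               stringsAsFactors = FALSE)
  })
  list(pairs = do.call(rbind, pairs), preferred = mat)
}

#' Read a stored RSCU profile
#'
#' Reads a minimal RSCU profile TSV (`codon`, `aa3`, `rscu` columns, RNA
#' codon spelling) such as the example profiles shipped under
#' `inst/extdata`, and returns a classified RSCU table compatible with
#' [preferred_codons()] and [preferred_codon_agreement()].
#'
#' @param path path to the TSV.
#' @return classified RSCU table (see [classify_codons()]).
#' @examples
#' p <- system.file("extdata", "rscu_profile_host_plant.tsv",
#'                  package = "codonbias")
#' head(preferred_codons(read_rscu_profile(p)))
#' @export
read_rscu_profile <- function(path) {
  df <- read_cub_tsv(path)
  stopifnot(all(c("codon", "rscu") %in% names(df)))
  tab <- CODON_TABLE
  i <- match(to_dna(df$codon), tab$codon)
  if (anyNA(i)) stop("unknown codon in RSCU profile: ",
                     df$codon[which(is.na(i))[1L]])
  out <- data.frame(codon = to_rna(tab$codon[i]), aa = tab$aa[i],
                    aa3 = tab$aa3[i], family_size = tab$family_size[i],
                    count = NA_integer_, rscu = df$rscu,
                    stringsAsFactors = FALSE)
  classify_codons(out)
}
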