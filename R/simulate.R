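# Synthetic CDS generator with known ground truth.
#
# Mechanism. The genetic code fixes a gene's first/second codon positions
# once its amino acids are chosen, while the third position is (mostly)
# free to vary synonymously.  The generator therefore controls GC12 through
# the amino-acid composition and GC3 through the synonymous choice:
#
#   * amino acids are drawn with probability proportional to
#     family_size * exp(theta * gc12_aa), where gc12_aa is the expected
#     GC content of positions 1-2 for that amino acid under the current
#     within-family codon distribution;
#   * within a family, codon j is drawn with probability proportional to
#     exp(kappa * [j is the family's preferred codon] + eta * gc3_j),
#     where gc3_j is 1 for G/C-ending codons;
#   * per gene, the tilts (theta, eta) are solved so that the expected
#     GC12 and GC3 equal the gene's targets; the GC12 target follows the
#     configured neutrality line GC12 = intercept + slope * GC3 + noise.
#
# Both targets are therefore enforced in expectation; the realized values
# recorded in the truth table are recomputed from the emitted sequence and
# round-trip exactly through the composition module.
#
# Reproducibility: each gene uses its own RNG stream seeded by a stable
# hash of (seed, gene index), so the same seed yields byte-identical FASTA
# and a change of n_genes does not reshuffle earlier genes.

# internal: per-position GC indicator tables for the 61 sense codons
SIM_CODON_INFO <- local({
  s <- CODON_TABLE[CODON_TABLE$aa != "*", ]
  aa_names <- sort(unique(s$aa))
  fam_idx <- match(s$aa, aa_names)
  agg <- matrix(0, length(aa_names), nrow(s),
                dimnames = list(aa_names, s$codon))
  agg[cbind(fam_idx, seq_len(nrow(s)))] <- 1
  list(
    codon = s$codon,
    aa = s$aa,
    aa_names = aa_names,
    fam_idx = fam_idx,
    agg = agg,   # family x codon aggregation matrix (fast tapply)
    gc3 = as.numeric(s$base3 %in% c("G", "C")),
    gc12 = (as.numeric(s$base1 %in% c("G", "C")) +
              as.numeric(s$base2 %in% c("G", "C"))) / 2
  )
})

# internal: default preferred codon per degenerate family - the
# alphabetically first T-ending codon, else the first A-ending one
# (AT-ending preference, the regime typical of AT-rich genomes).
default_preferred <- function() {
  vapply(AA_FAMILIES[DEGENERATE_AA], function(cods) {
    third <- substr(cods, 3, 3)
    if (any(third == "T")) sort(cods[third == "T"])[1L]
    else sort(cods[third == "A"])[1L]
  }, character(1))
}

#' Configuration for the synthetic CDS generator
#'
#' Defaults emulate a comparative codon-usage study input: a few hundred
#' genes of 100-700 codons, a wide per-gene GC3 spread, a shallow
#' neutrality slope (selection-dominated regime) and weak synonymous bias
#' (dataset mean ENC around 45-50).
#'
#' @param n_genes number of genes.
#' @param len_range inclusive range of gene lengths in internal codons
#'   (excluding the ATG start and the stop codon), drawn uniformly.
#' @param gc3_range per-gene GC3 target drawn uniformly from this range
#'   (fractions); `NULL` disables GC3 tilting (uniform synonymous choice
#'   apart from `kappa`).
#' @param slope,intercept,gc12_sd neutrality line: each gene's GC12 target
#'   is `intercept + slope * GC3_target + N(0, gc12_sd)` (fractions);
#'   `slope = NULL` disables GC12 control (neutral amino-acid usage).
#' @param kappa synonymous bias strength, >= 0; 0 gives uniform usage
#'   within families, larger values concentrate usage on the preferred
#'   codon of each family.
#' @param preferred named character vector amino acid -> codon (DNA or RNA)
#'   receiving the `kappa` preference; default: AT-ending codons (see
#'   details in the generator source).
#' @param stop_codons stop codons drawn uniformly per gene.
#' @param seed integer seed; identical configurations reproduce identical
#'   datasets byte for byte.
#' @return object of class `"cub_sim_config"`.
#' @export
sim_config <- function(n_genes = 200, len_range = c(100, 700),
                       gc3_range = c(0.2, 0.8),
                       slope = 0.15, intercept = 0.35, gc12_sd = 0.02,
                       kappa = 1, preferred = NULL,
                       stop_codons = STOP_CODONS, seed = 1) {
  stopifnot(n_genes >= 1, length(len_range) == 2L,
            len_range[1L] >= 33, len_range[1L] <= len_range[2L],
            kappa >= 0, all(stop_codons %in% STOP_CODONS),
            is.numeric(seed), seed == round(seed))
  if (!is.null(gc3_range))
    stopifnot(length(gc3_range) == 2L, gc3_range[1L] >= 0,
              gc3_range[2L] <= 1, gc3_range[1L] <= gc3_range[2L])
  if (!is.null(slope)) stopifnot(is.numeric(intercept), gc12_sd >= 0)
  pref <- if (is.null(preferred)) default_preferred()
          else stats::setNames(to_dna(preferred), names(preferred))
  structure(list(n_genes = as.integer(n_genes), len_range = len_range,
                 gc3_range = gc3_range, slope = slope,
                 intercept = intercept, gc12_sd = gc12_sd,
                 kappa = kappa, preferred = pref,
                 stop_codons = stop_codons, seed = as.integer(seed)),
            class = "cub_sim_config")
}

# internal: within-family codon probabilities for given (eta, kappa)
sim_codon_probs <- function(eta, kappa, preferred) {
  info <- SIM_CODON_INFO
  w <- exp(kappa * (info$codon %in% preferred) + eta * info$gc3)
  fam_tot <- as.vector(info$agg %*% w)
  w / fam_tot[info$fam_idx]
}

# internal: expected GC3 / GC12 per amino acid given eta
sim_aa_expectations <- function(eta, kappa, preferred) {
  info <- SIM_CODON_INFO
  p <- sim_codon_probs(eta, kappa, preferred)
  list(gc3 = stats::setNames(as.vector(info$agg %*% (p * info$gc3)),
                             info$aa_names),
       gc12 = stats::setNames(as.vector(info$agg %*% (p * info$gc12)),
                              info$aa_names))
}

# internal: amino-acid probabilities given theta and per-aa gc12
sim_aa_probs <- function(theta, gc12_aa) {
  w <- FAMILY_SIZE[names(gc12_aa)] * exp(theta * gc12_aa)
  w / sum(w)
}

# internal: solve (theta, eta) so that expected GC12/GC3 hit the targets;
# either target may be NA (no tilt on that margin).  Returns the tilts and
# the within-family codon probabilities.  Infeasible targets are met as
# closely as the code allows (tilts clamped at +/- bound).
sim_solve_tilts <- function(gc3_target, gc12_target, kappa, preferred,
                            bound = 30, iter = 3) {
  theta <- 0; eta <- 0
  for (it in seq_len(iter)) {
    ex <- sim_aa_expectations(eta, kappa, preferred)
    if (!is.na(gc12_target)) {
      f12 <- function(th) sum(sim_aa_probs(th, ex$gc12) * ex$gc12) - gc12_target
      theta <- if (f12(-bound) >= 0) -bound else if (f12(bound) <= 0) bound
               else stats::uniroot(f12, c(-bound, bound), tol = 1e-6)$root
    }
    if (!is.na(gc3_target)) {
      pa <- sim_aa_probs(theta, ex$gc12)
      f3 <- function(et) {
        e3 <- sim_aa_expectations(et, kappa, preferred)$gc3
        sum(pa * e3) - gc3_target
      }
      eta <- if (f3(-bound) >= 0) -bound else if (f3(bound) <= 0) bound
             else stats::uniroot(f3, c(-bound, bound), tol = 1e-6)$root
    } else break
  }
  ex <- sim_aa_expectations(eta, kappa, preferred)
  list(theta = theta, eta = eta,
       aa_probs = sim_aa_probs(theta, ex$gc12),
       codon_probs = sim_codon_probs(eta, kappa, preferred))
}

# internal: stable per-gene seed below 2^31
gene_seed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) * 48271 + i * 9973) %% 2147483399) + 1L
}

# internal: sample one gene body (internal codons) given probabilities
sim_sample_codons <- function(n_codons, aa_probs, codon_probs) {
  info <- SIM_CODON_INFO
  aa_seq <- sample(names(aa_probs), n_codons, replace = TRUE,
                   prob = aa_probs)
  cods <- character(n_codons)
  for (a in unique(aa_seq)) {
    pos <- which(aa_seq == a)
    fam <- which(info$aa == a)
    cods[pos] <- if (length(fam) == 1L) info$codon[fam]
      else sample(info$codon[fam], length(pos), replace = TRUE,
                  prob = codon_probs[fam])
  }
  cods
}

#' Generate a synthetic CDS dataset with known ground truth
#'
#' @param config a [sim_config()] object.
#' @return object of class `"cub_sim"`: `sequences` (named character, each
#'   a full CDS `ATG ... stop` that passes [qc_filter()]), `truth` (per
#'   gene: targets, realized GC3/GC12 as recomputed from the sequence, and
#'   length), and `config`.
#' @examples
#' sim <- simulate_cds(sim_config(n_genes = 5, seed = 42))
#' sim$truth
#' @export
simulate_cds <- function(config) {
  stopifnot(inherits(config, "cub_sim_config"))
  n <- config$n_genes
  ids <- sprintf("gene_%04d", seq_len(n))
  seqs <- character(n)
  truth <- data.frame(gene_id = ids, length_codons = integer(n),
                      gc3_target = NA_real_, gc12_target = NA_real_,
                      gc3_realized = NA_real_, gc12_realized = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    set.seed(gene_seed(config$seed, i))
    len <- sample(config$len_range[1L]:config$len_range[2L], 1L)
    gc3_t <- if (is.null(config$gc3_range)) NA_real_
             else stats::runif(1, config$gc3_range[1L], config$gc3_range[2L])
    gc12_t <- if (is.null(config$slope)) NA_real_
              else config$intercept + config$slope * gc3_t +
                   stats::rnorm(1, 0, config$gc12_sd)
    if (!is.na(gc12_t)) gc12_t <- min(max(gc12_t, 0.05), 0.95)
    tilt <- sim_solve_tilts(gc3_t, gc12_t, config$kappa, config$preferred)
    body <- sim_sample_codons(len, tilt$aa_probs, tilt$codon_probs)
    stop_c <- sample(config$stop_codons, 1L)
    seqs[i] <- paste(c(START_CODON, body, stop_c), collapse = "")
    counts <- count_codons(seqs[i])
    gc <- gc_by_position(counts)
    truth$length_codons[i] <- len + 2L
    truth$gc3_target[i] <- gc3_t
    truth$gc12_target[i] <- gc12_t
    truth$gc3_realized[i] <- gc[["GC3"]] / 100
    truth$gc12_realized[i] <- gc[["GC12"]] / 100
  }
  names(seqs) <- ids
  structure(list(sequences = seqs, truth = truth, config = config),
            class = "cub_sim")
}

#' @export
print.cub_sim <- function(x, ...) {
  cat("Synthetic CDS dataset: ", length(x$sequences), " genes, ",
      "lengths ", min(x$truth$length_codons), "-",
      max(x$truth$length_codons), " codons\n", sep = "")
  cat("kappa = ", x$config$kappa, ", neutrality slope = ",
      if (is.null(x$config$slope)) "none" else x$config$slope,
      ", seed = ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Generate one gene whose codon usage follows a target RSCU profile
#'
#' Amino acids are drawn with probability proportional to family size and
#' codons multinomially within each family with probability
#' `rscu_j / family_size`, so the expected RSCU of the emitted gene equals
#' the target and the empirical RSCU converges to it with gene length.
#'
#' @param target_rscu an [rscu()]-style table (`codon`, `aa`, `rscu`
#'   columns) or a named numeric vector of RSCU values (RNA or DNA codon
#'   names); families not covered fall back to uniform usage.
#' @param n_codons number of internal codons to draw (the emitted CDS has
#'   `n_codons + 2` codons including start and stop).
#' @param seed integer seed.
#' @return a single CDS string (named with `"gene_rscu"`), QC-valid.
#' @export
generate_gene_from_rscu <- function(target_rscu, n_codons, seed = 1) {
  stopifnot(n_codons >= 1)
  if (is.data.frame(target_rscu)) {
    vals <- stats::setNames(target_rscu$rscu, to_dna(target_rscu$codon))
  } else {
    vals <- stats::setNames(as.numeric(target_rscu),
                            to_dna(names(target_rscu)))
  }
  info <- SIM_CODON_INFO
  p <- rep(1, length(info$codon))
  names(p) <- info$codon
  have <- intersect(names(vals), info$codon)
  p[have] <- pmax(vals[have], 0)
  p[is.na(p)] <- 0
  fam_tot <- tapply(p, info$aa, sum)
  # families with all-zero mass fall back to uniform
  for (a in names(fam_tot)[fam_tot == 0]) p[info$aa == a] <- 1
  fam_tot <- tapply(p, info$aa, sum)[info$aa]
  codon_probs <- p / fam_tot
  aa_probs <- FAMILY_SIZE / sum(FAMILY_SIZE)
  set.seed(as.integer(seed))
  body <- sim_sample_codons(n_codons, aa_probs, codon_probs)
  stop_c <- sample(STOP_CODONS, 1L)
  stats::setNames(paste(c(START_CODON, body, stop_c), collapse = ""),
                  "gene_rscu")
}
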