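test_that("RSCU matches hand computation and conserves family sums", {
  expect_warning(r <- rscu(c(GCT = 2, GCC = 2, GCA = 2, GCG = 2)),
                 "preferred-codon tie")
  expect_equal(r$rscu[r$aa == "A"], rep(1, 4))
  r2 <- rscu(c(GCT = 3, GCC = 1, GCA = 0, GCG = 0))
  ala <- r2[r2$aa == "A", ]
  expect_equal(stats::setNames(ala$rscu, ala$codon),
               c(GCA = 0, GCC = 1, GCG = 0, GCU = 3))
  # unobserved families are NA, not zero
  expect_true(all(is.na(r2$rscu[r2$aa == "K"])))
  for (seed in 1:25) {
    cts <- random_counts(seed)
    rr <- suppressWarnings(rscu(cts))
    sums <- tapply(rr$rscu, rr$aa, sum)
    sizes <- tapply(rr$family_size, rr$aa, unique)
    obs <- !is.na(sums)
    expect_equal(as.numeric(sums[obs]), as.numeric(sizes[obs]),
                 tolerance = 1e-9)
  }
})

test_that("threshold flags use strict inequalities and stop rows are kept", {
  cts <- stats::setNames(integer(64), genetic_code()$codon)
  # Phe family engineered to RSCU exactly (1.6, 0.4); Lys exactly (0.6, 1.4)
  cts[c("TTT", "TTC")] <- c(8, 2)
  cts[c("AAA", "AAG")] <- c(3, 7)
  r <- rscu(cts)
  expect_equal(r$rscu[r$codon == "UUU"], 1.6)
  expect_false(r$overrepresented[r$codon == "UUU"])  # strict >
  expect_equal(r$rscu[r$codon == "AAA"], 0.6)
  expect_false(r$underrepresented[r$codon == "AAA"]) # strict <
  expect_true(r$overrepresented[r$codon == "UUU"] ==
                FALSE && r$high[r$codon == "UUU"])
  r2 <- rscu(c(TTT = 9, TTC = 1))
  expect_true(r2$overrepresented[r2$codon == "UUU"])
  expect_true(r2$underrepresented[r2$codon == "UUC"])
  # stop family reported as Ter rows
  r3 <- rscu(c(TAA = 2, TAG = 1, TGA = 0))
  ter <- r3[r3$aa3 == "Ter", ]
  expect_equal(sum(ter$rscu), 3)
  expect_false(any(ter$preferred))
})

test_that("Wright F-hat and ENC match hand computations", {
  cts <- stats::setNames(integer(64), genetic_code()$codon)
  cts[c("TTT", "TTC")] <- c(3, 1)
  Fbar <- codonbias:::enc_class_F(cts)
  expect_equal(Fbar[["2"]], (4 * (0.75^2 + 0.25^2) - 1) / 3)  # 0.5
  expect_equal(Fbar[["2"]], 0.5)
  # one codon per family: every F-hat is 1, ENC = 2 + 9 + 1 + 5 + 3 = 20
  expect_equal(enc(single_codon_counts(each = 5)), 20)
  # exactly uniform usage at large length: ENC capped near 61
  big <- uniform_family_counts(each = 100000 %/% 59)
  expect_equal(enc(big), 61, tolerance = 0.5 / 61)
})

test_that("ENC equals an independent per-family oracle on random genes", {
  naive_enc <- function(counts) {
    tab <- genetic_code()
    fams <- split(tab$codon[tab$aa != "*"], tab$aa[tab$aa != "*"])
    fams <- fams[!(names(fams) %in% c("M", "W"))]
    Fh <- list("2" = c(), "3" = c(), "4" = c(), "6" = c())
    for (a in names(fams)) {
      x <- counts[fams[[a]]]
      n <- sum(x)
      if (n < 2) next
      k <- as.character(length(fams[[a]]))
      Fh[[k]] <- c(Fh[[k]], (n * sum((x / n)^2) - 1) / (n - 1))
    }
    Fb <- vapply(Fh, function(v) if (length(v)) mean(v) else NA_real_, 0)
    if (is.na(Fb[["3"]]) && !anyNA(Fb[c("2", "4", "6")]))
      Fb[["3"]] <- mean(Fb[c("2", "4")])
    if (anyNA(Fb) || any(Fb <= 0)) return(NA_real_)
    min(61, 2 + 9 / Fb[["2"]] + 1 / Fb[["3"]] + 5 / Fb[["4"]] + 3 / Fb[["6"]])
  }
  for (seed in 1:15) {
    cts <- count_codons(random_cds(250, seed + 400))
    expect_equal(enc(cts), naive_enc(cts), tolerance = 1e-12)
  }
})

test_that("ENC decreases monotonically along the generator bias ladder", {
  mean_enc <- vapply(c(0, 0.5, 1, 2, 4), function(k) {
    sim <- simulate_cds(sim_config(n_genes = 40, len_range = c(150, 300),
                                   gc3_range = NULL, slope = NULL,
                                   kappa = k, seed = 99))
    mean(apply(codon_count_matrix(sim$sequences), 1, enc), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_enc) < 0))
  expect_true(all(mean_enc >= 20 & mean_enc <= 61))
})

test_that("reference weights and CAI behave as specified", {
  cts <- stats::setNames(integer(64), genetic_code()$codon)
  cts[c("TTT", "TTC")] <- c(3, 1)
  w <- reference_weights(cts)
  expect_equal(w[["TTT"]], 1)
  expect_equal(w[["TTC"]], 1 / 3)
  expect_equal(w[["AAA"]], 1)  # untouched family stays uninformative
  # floor for reference-absent codons in an observed family
  cts0 <- stats::setNames(integer(64), genetic_code()$codon)
  cts0[c("TTT", "TTC")] <- c(5, 0)
  expect_equal(reference_weights(cts0)[["TTC"]], 0.01)
  # scale invariance of the reference counts
  ref <- random_counts(7)
  expect_equal(reference_weights(ref), reference_weights(ref * 13))
  # geometric-mean examples
  wts <- stats::setNames(rep(1, 59), codonbias:::CUB_CODONS)
  gene <- stats::setNames(integer(64), genetic_code()$codon)
  gene[c("TTT", "TTC")] <- c(1, 1)
  wts[["TTC"]] <- 0.25
  expect_equal(cai(gene, wts), 0.5)       # sqrt(1 * 0.25)
  gene2 <- gene; gene2[["TTC"]] <- 0
  expect_equal(cai(gene2, wts), 1)        # only max-weight codons
})

test_that("CBI and Fop match their closed forms", {
  tab <- genetic_code()
  opt <- optimal_codon_set(suppressWarnings(rscu(single_codon_counts(4))))
  expect_length(opt, 18L)
  expect_true(all(substr(opt, 1, 3) %in% tab$codon))
  # gene using only optimal codons
  only_opt <- stats::setNames(integer(64), tab$codon)
  only_opt[opt] <- 3
  expect_equal(cbi(only_opt, opt), 1)
  expect_equal(fop(only_opt, opt), 1)
  # perfectly uniform usage: N_opt = N_ran so CBI = 0
  expect_equal(cbi(uniform_family_counts(6), opt), 0)
  # Fop as a plain ratio: twofold amino acid used 4 times, optimal twice
  gene <- stats::setNames(integer(64), tab$codon)
  gene[c("TTT", "TTC")] <- c(2, 2)
  opt_f <- stats::setNames("TTT", "F")
  expect_equal(fop(gene, opt_f), 0.5)
  # random fixture vs naive ratio oracle
  for (seed in 1:10) {
    cts <- random_counts(seed + 20)
    deg <- tab$codon[tab$aa != "*" & tab$family_size >= 2 &
                       !(tab$codon %in% c("ATG", "TGG"))]
    expect_equal(fop(cts, opt), sum(cts[opt]) / sum(cts[deg]))
  }
})

test_that("preferred/optimal codon ties break lexicographically, user set wins", {
  cts <- stats::setNames(integer(64), genetic_code()$codon)
  cts[c("TTT", "TTC")] <- c(4, 4)
  expect_warning(r <- rscu(cts), "tie for F")
  expect_identical(r$codon[r$preferred & r$aa == "F"], "UUC")  # UUC < UUU
  user <- c(F = "UUU")
  expect_identical(unname(optimal_codon_set(r, user = user)), "TTT")
  expect_error(optimal_codon_set(r, user = c(F = "AAA")), "not encoding")
})

test_that("GRAVY and AROMO match the residue tables", {
  expect_equal(gravy(strrep("I", 12)), 4.5)
  expect_equal(gravy(strrep("R", 5)), -4.5)
  expect_equal(gravy("IR"), 0)
  expect_equal(aromo("FYW"), 1)
  expect_equal(aromo("AAAA"), 0)
  expect_equal(aromo("FAYA"), 0.5)
  expect_error(gravy("JZ"), "unknown residue")
})

test_that("the per-gene index table is complete and in range", {
  sim <- simulate_cds(sim_config(n_genes = 20, len_range = c(120, 250),
                                 seed = 5))
  idx <- gene_indices(sim$sequences)
  expect_identical(nrow(idx), 20L)
  expect_true(all(idx$ENC >= 20 & idx$ENC <= 61, na.rm = TRUE))
  expect_true(all(idx$CAI > 0 & idx$CAI <= 1))
  expect_true(all(idx$Fop >= 0 & idx$Fop <= 1))
  expect_true(all(idx$CBI >= -1 & idx$CBI <= 1))
  expect_true(all(idx$AROMO >= 0 & idx$AROMO <= 1))
  expect_true(all(c("GC3", "GC12", "A3s", "L_sym", "L_aa") %in% names(idx)))
  # top-ENC reference variant runs and stays in range
  idx2 <- gene_indices(sim$sequences, cai_ref = "top_enc", top_enc_q = 0.2)
  expect_true(all(idx2$CAI > 0 & idx2$CAI <= 1))
})

test_that("CAI is near 0 under its self-reference only for unbiased sets", {
  # a strongly biased dataset has high self-referential CAI by construction
  sim <- simulate_cds(sim_config(n_genes = 15, len_range = c(150, 250),
                                 gc3_range = NULL, slope = NULL, kappa = 4,
                                 seed = 31))
  idx <- gene_indices(sim$sequences)
  expect_gt(mean(idx$CAI), 0.7)
})
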