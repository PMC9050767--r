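test_that("positional base fractions match direct tallies", {
  f <- positional_base_fractions(c(AAA = 1, TTT = 1))
  expect_equal(unname(f[, "A"]), rep(0.5, 3))
  expect_equal(unname(f[, "T"]), rep(0.5, 3))
  f2 <- positional_base_fractions(c(GCG = 2))
  expect_equal(f2["pos1", "G"], 1)
  expect_equal(f2["pos2", "C"], 1)
  expect_equal(f2["pos3", "G"], 1)
  expect_equal(unname(rowSums(f2)), rep(1, 3))
  # brute-force oracle: expand counts to codon strings and tally by hand
  for (seed in 1:5) {
    cts <- random_counts(seed)
    cods <- rep(names(cts), cts)
    f3 <- positional_base_fractions(cts)
    for (pos in 1:3) {
      tally <- table(factor(substr(cods, pos, pos),
                            levels = c("A", "C", "G", "T")))
      expect_equal(unname(f3[pos, ]), as.numeric(tally) / length(cods))
    }
  }
})

test_that("positional GC obeys its algebraic identities", {
  gc <- gc_by_position(count_codons(make_cds(rep("GCG", 10))))
  expect_equal(unname(gc[c("GC1", "GC2", "GC3", "GC")]), rep(100, 4))
  expect_equal(gc[["AT3"]], 0)
  gc0 <- gc_by_position(count_codons(make_cds(rep("ATA", 10))))
  expect_equal(gc0[["GC"]], 0)
  expect_equal(gc0[["AT"]], 100)
  for (seed in 1:10) {
    cts <- random_counts(seed + 50)
    gcr <- gc_by_position(cts)
    f <- positional_base_fractions(cts)
    expect_equal(sum(100 * colMeans(f)), 100, tolerance = 1e-9)
    expect_equal(gcr[["AT"]], 100 - gcr[["GC"]])
    expect_equal(gcr[["GC12"]], (gcr[["GC1"]] + gcr[["GC2"]]) / 2)
    expect_equal(gcr[["AT3"]], 100 - gcr[["GC3"]])
    expect_equal(gcr[["AT2"]], 100 - gcr[["GC2"]])
  }
})

test_that("silent-site propensities follow the availability convention", {
  # only degenerate codon used is GGA (Gly); Trp does not count as silent
  cts <- count_codons(make_cds(c("GGA", "GGA", "TGG")))
  s <- silent_site_composition(cts)
  expect_equal(s[["A3s"]], 100)
  expect_equal(s[["G3s"]], 0)
  expect_equal(s[["T3s"]], 0)
  expect_equal(s[["C3s"]], 0)
})

test_that("uniform synonymous usage gives the enumerated availability fractions", {
  cts <- uniform_family_counts(each = 7)
  s <- silent_site_composition(cts)
  # oracle: exhaustive enumeration over the code table
  tab <- genetic_code()
  deg <- tab[tab$aa != "*" & tab$family_size >= 2 &
               !(tab$codon %in% c("ATG", "TGG")), ]
  for (b in c("A", "T", "G", "C")) {
    fams_with_b <- unique(deg$aa[substr(deg$codon, 3, 3) == b])
    num <- sum(substr(deg$codon, 3, 3) == b)
    den <- sum(deg$aa %in% fams_with_b)
    expect_equal(s[[paste0(b, "3s")]], 100 * num / den, tolerance = 1e-12)
  }
})

test_that("composition records carry consistent synonymous/total lengths", {
  cds <- make_cds(c("GGA", "GGA", "TGG", "AAA"))
  rec <- gene_composition(cds)
  expect_equal(rec$L_sym, 3)   # GGA, GGA, AAA
  expect_equal(rec$L_aa, 4)    # + TGG (start excluded by default)
  rec2 <- gene_composition(cds, include_start = TRUE)
  expect_equal(rec2$L_aa, 5)
})

test_that("dataset means equal the column-average oracle", {
  one <- composition_table(c(g = random_cds(60, 1)))
  expect_equal(unname(unlist(composition_summary(one)["mean", ])),
               unname(unlist(one[1, -1])))
  seqs <- c(lo = make_cds(rep(c("GCA", "ATA"), 10)),
            hi = make_cds(rep(c("GCC", "GGA"), 10)))
  comp <- composition_table(seqs)
  means <- composition_summary(comp)["mean", ]
  expect_equal(means$GC, mean(comp$GC))
  seqs40 <- stats::setNames(vapply(1:40, function(s) random_cds(80, s),
                                   character(1)), paste0("g", 1:40))
  comp40 <- composition_table(seqs40)
  sm <- composition_summary(comp40)["mean", ]
  for (col in names(sm)) {
    expect_equal(sm[[col]], mean(comp40[[col]]), tolerance = 1e-12)
    expect_gte(sm[[col]], min(comp40[[col]]))
    expect_lte(sm[[col]], max(comp40[[col]]))
  }
})

test_that("pooled composition equals the count-weighted mean of genes", {
  seqs <- stats::setNames(vapply(1:8, function(s) random_cds(30 + 5 * s, s),
                                 character(1)), paste0("g", 1:8))
  m <- codon_count_matrix(seqs)
  pooled <- gc_by_position(colSums(m))
  w <- rowSums(m) / sum(m)
  per_gene <- t(apply(m, 1, gc_by_position))
  expect_equal(pooled[["GC"]], sum(w * per_gene[, "GC"]), tolerance = 1e-9)
  expect_equal(pooled[["GC3"]], sum(w * per_gene[, "GC3"]), tolerance = 1e-9)
})
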