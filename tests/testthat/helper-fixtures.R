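# Shared fixture builders: everything is generated in code at test time.

# wrap internal codons into a full CDS (ATG ... stop)
make_cds <- function(codons, stop = "TAA") {
  paste(c("ATG", codons, stop), collapse = "")
}

# random valid CDS of n internal codons drawn uniformly from sense codons
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  sense <- genetic_code()
  sense <- sense$codon[sense$aa != "*"]
  make_cds(sample(sense, n_codons, replace = TRUE))
}

# random non-negative count vector over the 64 codons
random_counts <- function(seed, lambda = 5) {
  set.seed(seed)
  cod <- genetic_code()$codon
  stats::setNames(rpois(64, lambda), cod)
}

# naive triplet-scan codon counter (independent oracle for count_codons)
naive_codon_counts <- function(seq, include_start = FALSE,
                               include_stop = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  cods <- character(0)
  for (i in seq(1, nchar(seq) - 2, by = 3))
    cods <- c(cods, substr(seq, i, i + 2))
  if (!include_stop && cods[length(cods)] %in% stops)
    cods <- cods[-length(cods)]
  if (!include_start && cods[1] == "ATG") cods <- cods[-1]
  out <- stats::setNames(integer(64), genetic_code()$codon)
  for (cd in cods) out[cd] <- out[cd] + 1L
  out
}

# uniform-usage count vector: `each` occurrences of every codon of every
# degenerate family (exactly uniform within families)
uniform_family_counts <- function(each = 10) {
  tab <- genetic_code()
  deg <- tab$codon[tab$aa != "*" & tab$family_size >= 2 &
                     !(tab$codon %in% c("ATG", "TGG"))]
  out <- stats::setNames(integer(64), tab$codon)
  out[deg] <- each
  out
}

# one-codon-per-family count vector (maximal bias)
single_codon_counts <- function(each = 5) {
  tab <- genetic_code()
  tab <- tab[tab$aa != "*" & tab$family_size >= 2 &
               !(tab$codon %in% c("ATG", "TGG")), ]
  first <- tapply(tab$codon, tab$aa, function(x) sort(x)[1])
  out <- stats::setNames(integer(64), genetic_code()$codon)
  out[first] <- each
  out
}
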