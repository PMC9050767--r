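Package: codonbias
Title: Codon Usage Bias Analysis for Protein-Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative codon usage bias (CUB) analysis of
    protein-coding sequences, as applied in host-pathogen molecular
    evolution studies. Reads and quality-filters CDS FASTA files, computes
    nucleotide composition (positional GC, silent-site base propensities),
    the classical CUB index suite (RSCU with preferred/over/under-represented
    codon classification, Wright's effective number of codons, codon
    adaptation index, codon bias index, frequency of optimal codons,
    GRAVY hydropathy and aromaticity), evolutionary-force diagnostics
    (ENC-GC3 plot against Wright's null curve, parity rule 2 plot at
    fourfold-degenerate third positions, neutrality regression of GC12 on
    GC3, index correlation tables), correspondence analysis of the gene by
    codon RSCU matrix, codon-pair context ranking and amino-acid usage
    summaries. Includes a synthetic CDS generator with controllable GC3
    spread, synonymous bias strength and neutrality slope so that every
    analysis stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    withr
Config/testthat/edition: 3
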