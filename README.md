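# codonbias

Comparative **codon usage bias (CUB)** analysis of protein-coding
sequences, for molecular evolution and host–pathogen studies.

Synonymous codons are not used equally. The degree and direction of that
inequality carries information about directional mutation pressure and
about selection (e.g. for translational efficiency), and comparing it
between a host and its pathogens reveals whether their codon usage has
converged. `codonbias` implements the complete standard workflow on CDS
FASTA input:

- **QC**: ATG start, valid stop, no internal stop, no ambiguous base,
  length ≥ 100 nt and divisible by 3, with a per-gene rejection report.
- **Composition**: base content, positional GC (GC1, GC2, GC3,
  GC12 = (GC1+GC2)/2), silent-site propensities A3s/T3s/G3s/C3s.
- **Index suite** (per gene): RSCU with preferred / over- (RSCU > 1.6) /
  under-represented (RSCU < 0.6) codon classification; Wright's effective
  number of codons `ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆` (20 =
  maximal bias, 61 = uniform); CAI (geometric mean of relative
  adaptiveness `w = RSCU/RSCUmax`); CBI = (N_opt − N_ran)/(N_tot − N_ran);
  Fop = N_opt/N_tot; GRAVY (Kyte–Doolittle) and aromaticity.
- **Force diagnostics**: ENC–GC3 plot against Wright's null curve
  `ENC_exp(s) = 2 + s + 29/(s² + (1−s)²)`; PR2 plot A3/(A3+T3) vs
  G3/(G3+C3) over fourfold-degenerate third positions; neutrality
  regression of GC12 on GC3 (selection share = 1 − slope); index
  correlation tables.
- **Correspondence analysis** of the gene × 59-codon RSCU matrix with
  inertia shares and AT-/GC-ending codon labels.
- **Codon context**: top adjacent codon pairs with preferred/identical
  flags; amino-acid usage with degeneracy-class roll-up.
- **Synthetic CDS generator** with controllable GC3 spread, neutrality
  slope and bias strength κ, providing exact ground truth for every stage.

## Worked example

```r
library(codonbias)

sim  <- simulate_cds(sim_config(n_genes = 50, seed = 2024))
prof <- codon_usage_profile(sim$sequences, label = "demo")
prof
#> Codon usage bias profile: demo
#>   genes analysed : 50 (0 rejected at QC)
#>   mean ENC 51.66 | CAI 0.825 | CBI 0.109 | Fop 0.399
#>   mean GC% 45.46 (GC3 52.66) | GRAVY -0.074 | AROMO 0.113
#>   neutrality slope 0.145 (r = 0.630, p = 9.49e-07)
#>   CoA axis 1: 45.13%, axis 2: 6.57% of inertia
```

Mean ENC ≈ 52 is the weak-bias regime typical of nuclear genes (the
generator was configured with κ = 1); the neutrality slope recovers the
configured 0.15 — read as "mutation pressure explains ~15% of the GC12
variation, selection/constraint the remaining ~85%". Per-codon detail:

```r
r <- prof$rscu
head(r[r$informative, c("codon", "aa3", "count", "rscu", "preferred")], 4)
#>  codon aa3 count      rscu preferred
#>    AAA Lys   545 1.1237113      TRUE
#>    AAC Asn   463 0.8869732     FALSE
#>    AAG Lys   425 0.8762887     FALSE
#>    AAU Asn   581 1.1130268      TRUE
```

`plot(prof, type = "enc" | "pr2" | "neutrality" | "coa" | "aa")` draws the
standard diagnostics. Multi-species runs write every table as TSV:

```r
run_pipeline(list(host = "host.fa", nematode = "nematode.fa"), "out/")
```

including a cross-species preferred-codon agreement table. Example RSCU
profiles of a medicinal host plant and two of its pathogens (a root-knot
nematode and a leaf-spot fungus) ship in `inst/extdata/`; the plant and
nematode profiles agree on 17 of 18 preferred codons, differing only at
Pro (CCU vs CCA), while plant and fungus share none — the kind of contrast
the agreement table is designed to surface.

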