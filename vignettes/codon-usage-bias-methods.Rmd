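---
title: "Methods: codon usage bias analysis with codonbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias analysis with codonbias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

# Scope and model

`codonbias` implements the standard comparative codon-usage-bias (CUB)
workflow used in host–pathogen molecular evolution studies: given one set of
protein-coding sequences (CDS) per species, it quantifies how unevenly
synonymous codons are used, and asks whether that unevenness looks like
directional mutation pressure, like selection (e.g. for translational
efficiency), or both.

The workflow is: quality control → nucleotide composition → RSCU and
preferred codons → per-gene index suite (ENC, CAI, CBI, Fop, GRAVY, AROMO) →
evolutionary-force diagnostics (ENC–GC3 plot, PR2 plot, neutrality
regression, correlation tables) → correspondence analysis of the gene ×
codon RSCU matrix → codon-pair context and amino-acid usage → cross-species
comparison of preferred codons.

# Quality control

A kept CDS must: be at least `min_length_nt` (default 100) nucleotides long,
start with ATG, end with a stop codon (UAA/UAG/UGA), contain no internal
in-frame stop, contain only A/C/G/T, and have length divisible by three.
Each rejected record is assigned the *first* failing rule, in that order, so
QC reports are deterministic. Internal stops are rejected rather than
truncated, which keeps downstream translation total. The 100-bp floor
limits the sampling error of per-gene indices; it is a tunable argument,
not a constant.

Only the standard genetic code is supported. Met (AUG) and Trp (UGG) have
no synonymous alternative and the three stops are not translated, so all
bias indices operate on the remaining 59 codons of the 18 degenerate amino
acids (9 twofold, Ile threefold, 5 fourfold, Leu/Ser/Arg sixfold).

# Composition conventions

Two third-position conventions coexist in this literature and both are
exposed:

* plain positional base fractions (each codon position sums to 1), used by
  the PR2 diagnostics and positional GC (GC1, GC2, GC3, GC12 = (GC1+GC2)/2);
* silent-site propensities A3s/T3s/G3s/C3s: for base *b*, the fraction of
  synonymous codon occurrences ending in *b* among codons whose family
  *offers b* at the third position. These need not sum to 100 — the
  signature of the classical composition tables this package mirrors.

Start and stop codons are excluded from composition and index tallies by
default (configurable), matching the index definitions; species-level
values are unweighted means over genes, with the pooled-count composition
reported alongside.

# The index suite

**RSCU**. RSCU~ij~ = x~ij~ / ((1/n~i~) Σ~j~ x~ij~). Within any observed
family the values sum to the family size; unobserved families are reported
as missing, not zero. Thresholds are the conventional strict inequalities:
RSCU > 1 high, < 1 low, > 1.6 overrepresented, < 0.6 underrepresented. The
preferred codon of an amino acid is its maximum-RSCU codon; ties are broken
toward the alphabetically first codon *with a logged warning*, because a
silent arbitrary choice would make cross-species agreement counts
irreproducible.

**ENC** (Wright). Per family with n ≥ 2 counted codons,
F̂ = (nΣp̂² − 1)/(n − 1); F̂ is averaged per degeneracy class and
ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆, capped at 61. If only the
threefold class (Ile) is missing, F̄₃ is imputed as (F̄₂+F̄₄)/2; with two
or more classes missing the gene's ENC is NA. This is the standard
treatment; the estimator is noisy for short genes (see *Calibration*).

**CAI**. Geometric mean over the gene's synonymous codon occurrences of
relative adaptiveness weights w~ij~ = RSCU~ij~/RSCU~i,max~ derived from a
reference set. No external reference is bundled: the default reference is
the pooled input dataset itself, with a `top_enc` option (lowest-ENC
quantile, a proxy for highly expressed genes) and user-supplied references.
Self-referential CAI is comparable within a dataset but not across studies
that used different references — published CAI values can therefore only be
matched approximately. Codons absent from the reference receive a floor
weight of 0.01 so the geometric mean stays finite; families entirely absent
get uninformative weights of 1.

**CBI and Fop** use an optimal codon set, one codon per degenerate amino
acid, defaulting to the dataset's maximum-RSCU (preferred) codons.
CBI = (N~opt~ − N~ran~)/(N~tot~ − N~ran~) with N~ran~ the uniform-usage
expectation; Fop = N~opt~/N~tot~. A subtlety verified by the test suite:
when the optimal set is *re-derived from the same data*, CBI acquires a
small positive winner's-curse bias even under perfectly uniform usage
(~+0.007 at 500 genes of default lengths), because the argmax picks
whichever codon happened to be most used. The null property "CBI = 0 in
expectation under uniform sampling" therefore is, and is tested, a
statement about a fixed a-priori optimal set.

**GRAVY** is the mean Kyte–Doolittle hydropathy of the translated protein
(positive = hydrophobic); **AROMO** the fraction of Phe/Tyr/Trp residues.

# Force diagnostics

**ENC–GC3**. Wright's null curve ENC = 2 + s + 29/(s² + (1−s)²) gives the
ENC expected when composition (GC3 = s) is the only source of bias. Genes
well below the curve show bias beyond composition (selection); genes near
it are compatible with mutation pressure alone. "Near" is quantified as a
±1 ENC band by default — the literature gives no tolerance, so it is an
explicit, configurable parameter.

**PR2**. Within the eight fully fourfold-degenerate codon boxes
(GCN, CGN, GGN, CUN, CCN, UCN, ACN, GUN — including the fourfold boxes of
the sixfold amino acids, Sueoka's convention), third-position A/T and G/C
should be interchangeable under symmetric mutation–selection balance. The
plot of A3/(A3+T3) against G3/(G3+C3) therefore centres on (0.5, 0.5) under
parity; displacement direction and magnitude describe the asymmetry. Genes
with a zero denominator are flagged invalid and excluded.

**Neutrality regression**. GC12 is regressed on GC3 across genes (OLS), with
the Pearson correlation and its two-tailed t-test. Slope near 1: the same
directional pressure drives all three positions (mutation dominates); slope
near 0: positions 1–2 are constrained while position 3 drifts (selection/
constraint dominates). The selection share is reported as 1 − slope, which
is exactly how the headline percentages of comparative CUB studies are
computed. If GC12 (or GC3) has zero variance the correlation is undefined
and reported as r = 0, p = 1.

**Correlations** between index columns use `stats::cor.test` (Pearson
default, Spearman by flag), pairwise-complete. Raw p-values are the primary
output, matching practice in this literature; a Benjamini–Hochberg column is
emitted alongside for users who want error control, but is never applied to
the primary values.

# Correspondence analysis

CA is run on the gene × 59-codon **RSCU** matrix (not raw counts — this
follows the convention of RSCU-based CUB studies and is deliberately
documented, because count-based CA weights genes by length and gives
different axes). Genes missing a family have that RSCU imputed as 0 (with a
message). The implementation is the textbook decomposition: divide by the
grand total, form standardized residuals S = D_r^{-1/2}(P − rcᵀ)D_c^{-1/2},
SVD, inertia share λᵢ/Σλ, symmetric principal coordinates for genes and
codons. Axis signs are arbitrary in CA, so a fixed convention (first
nonzero codon coordinate per axis made positive) makes runs reproducible.
Tests verify equivalence with both a brute-force eigendecomposition and
`vegan::cca` to 1e-8. Codons are labelled AT-ending/GC-ending for the
conventional biplot colouring; four axes are reported by default.

# Codon context and amino-acid usage

Adjacent codon pairs are counted within genes only (no boundary-spanning
pairs), start and stop codons included, and ranked by raw pooled count with
a deterministic alphabetical tie-break. The top-20 table flags pairs made
of two preferred codons and identical-codon pairs. Amino-acid usage is
tallied over translated residues with a degeneracy-class roll-up. Residual
or χ²-adjusted context maps are out of scope; only frequency ranking is
implemented.

# The synthetic generator

`simulate_cds()` produces datasets in which every downstream quantity has a
known truth. The genetic code fixes positions 1–2 once the amino acid is
chosen, and leaves position 3 (mostly) free, so the generator controls GC12
through amino-acid composition and GC3 through synonymous choice — the only
mechanism consistent with the code:

* per gene, a GC3 target is drawn from `gc3_range` and a GC12 target from
  the configured neutrality line (intercept + slope·GC3 + Gaussian noise);
* amino acids are drawn ∝ family_size · exp(θ·gc12), codons within a family
  ∝ exp(κ·[preferred] + η·gc3), with (θ, η) solved per gene so both targets
  hold *in expectation* (not exactly per gene — realized values carry
  multinomial noise and are recorded in the truth table by recomputing them
  from the emitted sequence, so they round-trip exactly);
* each gene has its own RNG stream derived from (seed, gene index), so runs
  are byte-reproducible and extending `n_genes` never reshuffles earlier
  genes.

Defaults describe a realistic study input: 200 genes of 100–700 codons,
GC3 spread 0.2–0.8, neutrality slope 0.15 with noise sd 0.02 around
intercept 0.35, κ = 1 (large-gene ENC ≈ 49, the weak-bias regime typical of
plant and pathogen nuclear genes), preference on the U-ending (else
A-ending) codon of each family. What the generator does **not** emulate:
amino-acid autocorrelation along real proteins, gene-family structure,
expression-correlated bias, dinucleotide effects and codon-pair (context)
preferences. Passing calibration tests therefore validates the estimators'
statistical behaviour, not any biological claim about real genomes; in
particular the codon-pair module can only be smoke-tested against the
generator, since context preferences are not simulated.

```{r, eval = FALSE}
sim <- simulate_cds(sim_config(n_genes = 200, seed = 1))
prof <- codon_usage_profile(sim$sequences, label = "synthetic")
prof
plot(prof, type = "enc")
```

# Numerical choices and degenerate inputs

* Codon count vectors are dense named 64-vectors in fixed alphabetical
  order; all tables derive from them, so pooling is exact integer addition.
* RSCU of an unobserved family is NA (never 0); CA imputes 0 only inside
  the fixed-layout matrix and logs how many cells were imputed.
* ENC is capped at 61; class means with F̄ ≤ 0 (possible for tiny genes)
  yield NA rather than a wild value.
* Preferred/optimal ties: alphabetical, warned. Codon-pair ties:
  alphabetical on (P1, P2).
* The tilt equations of the generator are solved by bisection
  (`uniroot`, tol 1e-6) with tilts clamped at ±30; unreachable targets are
  met as closely as the code allows (best effort).
* TSV outputs are written with a fixed schema header line, fixed column
  order and fixed formatting; repeated runs are byte-identical.

# Calibration results and known limitations

The test suite calibrates the pipeline against the generator: the
neutrality fit recovers a configured slope of 0.15 within ±0.03 in ≥95% of
100 seeded replicates (200 genes, noise sd 0.02); unbiased (κ = 0,
untilted) datasets centre the PR2 cloud on (0.5, 0.5) and a-priori-set CBI
on 0 within Monte-Carlo error; the bias ladder κ = 0, 0.5, 1, 2, 4 strictly
decreases mean ENC.

One calibration property fails by design of the estimator, not of the
implementation: Wright's ENC estimate has a standard deviation of roughly 3
ENC units for 100-codon genes under uniform usage, so with gene lengths
spanning 100–700 codons only ~90% of null genes fall within ±2 ENC units of
the expected curve (virtually all genes above ~350 codons do). ENC–GC3
classifications for genes shorter than ~200 codons should be read with that
noise floor in mind.

Other limitations: standard genetic code only; CAI is reference-relative
(see above); no tAI/SCUO/MILC/CDC indices; no codon-pair bias scores; no
bootstrap intervals on the neutrality slope (point estimates with
parametric p-values, as is conventional in this literature).

# Problem sizes

The shipped tests and the acceptance script use 6×8–10×6 matrices for the
CA oracle checks, 200-gene datasets for slope recovery and null
calibration, 500 genes for the CBI null, and 100 seeded replicates for the
recovery-rate estimate — sizes at which every Monte-Carlo tolerance above
has comfortable power while the whole suite runs in a couple of minutes.
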