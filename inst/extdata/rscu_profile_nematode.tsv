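# codonbias table v1
codon	aa3	rscu
AAA	Lys	0.671
AAC	Asn	0.498
AAG	Lys	0.329
AAU	Asn	1.440
ACA	Thr	1.501
ACC	Thr	0.547
ACG	Thr	0.304
ACU	Thr	1.598
AGA	Arg	1.791
AGC	Ser	0.613
AGG	Arg	0.385
AGU	Ser	1.071
AUA	Ile	0.612
AUC	Ile	0.470
AUG	Met	0.988
AUU	Ile	1.918
CAA	Gln	1.574
CAC	His	0.506
CAG	Gln	0.389
CAU	His	1.356
CCA	Pro	1.825
CCC	Pro	0.443
CCG	Pro	0.325
CCU	Pro	1.407
CGA	Arg	1.341
CGC	Arg	0.567
CGG	Arg	0.228
CGU	Arg	1.500
CUA	Leu	0.424
CUC	Leu	0.465
CUG	Leu	0.205
CUU	Leu	1.504
GAA	Glu	1.393
GAC	Asp	0.525
GAG	Glu	0.520
GAU	Asp	1.425
GCA	Ala	1.317
GCC	Ala	0.575
GCG	Ala	0.296
GCU	Ala	1.762
GGA	Gly	1.838
GGC	Gly	0.688
GGG	Gly	0.451
GGU	Gly	1.023
GUA	Val	0.717
GUC	Val	0.545
GUG	Val	0.521
GUU	Val	2.216
UAA	Ter	1.988
UAC	Tyr	0.459
UAG	Ter	0.394
UAU	Tyr	1.479
UCA	Ser	1.483
UCC	Ser	0.572
UCG	Ser	0.438
UCU	Ser	1.823
UGA	Ter	0.619
UGC	Cys	0.587
UGG	Trp	0.725
UGU	Cys	1.151
UUA	Leu	1.957
UUC	Phe	0.623
UUG	Leu	1.444
UUU	Phe	1.377
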