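# codonbias table v1
codon	aa3	rscu
AAA	Lys	1.337
AAC	Asn	0.569
AAG	Lys	0.638
AAU	Asn	1.405
ACA	Thr	1.239
ACC	Thr	0.806
ACG	Thr	0.397
ACU	Thr	1.559
AGA	Arg	1.701
AGC	Ser	0.499
AGG	Arg	0.762
AGU	Ser	1.139
AUA	Ile	0.849
AUC	Ile	0.635
AUG	Met	1.000
AUU	Ile	1.516
CAA	Gln	1.394
CAC	His	0.532
CAG	Gln	0.606
CAU	His	1.393
CCA	Pro	1.278
CCC	Pro	0.713
CCG	Pro	0.493
CCU	Pro	1.433
CGA	Arg	1.229
CGC	Arg	0.463
CGG	Arg	0.406
CGU	Arg	1.438
CUA	Leu	0.687
CUC	Leu	0.480
CUG	Leu	0.464
CUU	Leu	1.412
GAA	Glu	1.389
GAC	Asp	0.492
GAG	Glu	0.611
GAU	Asp	1.508
GCA	Ala	1.212
GCC	Ala	0.698
GCG	Ala	0.331
GCU	Ala	1.759
GGA	Gly	1.538
GGC	Gly	0.511
GGG	Gly	0.700
GGU	Gly	1.251
GUA	Val	1.283
GUC	Val	0.685
GUG	Val	0.486
GUU	Val	1.545
UAA	Ter	1.576
UAC	Tyr	0.491
UAG	Ter	0.731
UAU	Tyr	1.458
UCA	Ser	1.255
UCC	Ser	0.949
UCG	Ser	0.441
UCU	Ser	1.718
UGA	Ter	0.693
UGC	Cys	0.608
UGG	Trp	0.929
UGU	Cys	1.257
UUA	Leu	1.705
UUC	Phe	0.666
UUG	Leu	1.252
UUU	Phe	1.334
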