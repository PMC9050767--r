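# codonbias table v1
codon	aa3	rscu
AAA	Lys	0.475
AAC	Asn	1.482
AAG	Lys	1.525
AAU	Asn	0.518
ACA	Thr	0.901
ACC	Thr	1.521
ACG	Thr	0.673
ACU	Thr	0.905
AGA	Arg	0.600
AGC	Ser	1.253
AGG	Arg	0.761
AGU	Ser	0.571
AUA	Ile	0.384
AUC	Ile	1.679
AUG	Met	1.000
AUU	Ile	0.937
CAA	Gln	0.741
CAC	His	0.641
CAG	Gln	1.250
CAU	His	0.355
CCA	Pro	0.967
CCC	Pro	1.255
CCG	Pro	0.753
CCU	Pro	1.026
CGA	Arg	0.966
CGC	Arg	1.998
CGG	Arg	0.554
CGU	Arg	1.121
CUA	Leu	0.503
CUC	Leu	1.932
CUG	Leu	1.307
CUU	Leu	1.217
GAA	Glu	0.670
GAC	Asp	1.227
GAG	Glu	1.330
GAU	Asp	0.763
GCA	Ala	0.837
GCC	Ala	1.353
GCG	Ala	0.704
GCU	Ala	1.106
GGA	Gly	1.003
GGC	Gly	1.556
GGG	Gly	0.354
GGU	Gly	1.088
GUA	Val	0.572
GUC	Val	0.664
GUG	Val	1.752
GUU	Val	1.012
UAA	Ter	1.232
UAC	Tyr	1.474
UAG	Ter	1.130
UAU	Tyr	0.526
UCA	Ser	0.867
UCC	Ser	1.225
UCG	Ser	1.045
UCU	Ser	1.039
UGA	Ter	0.638
UGC	Cys	1.305
UGG	Trp	0.981
UGU	Cys	0.560
UUA	Leu	0.258
UUC	Phe	1.495
UUG	Leu	0.783
UUU	Phe	0.505
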