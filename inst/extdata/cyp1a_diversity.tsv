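# Published within-species diversity of M. fascicularis CYP1A1/CYP1A2
# coding sequences: chromosomes (N), segregating sites (S), per-site
# nucleotide diversity (pi) and its synonymous/nonsynonymous components,
# Tajima's D.
locus	N	S	pi	pi_S	pi_A	tajima_D
CYP1A1	20	7	0.00072	0.00219	0.00026	-1.446
CYP1A2	14	31	0.00462	0.00740	0.00375	-1.139
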