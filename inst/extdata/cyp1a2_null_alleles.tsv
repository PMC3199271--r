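# Published null-allele counts in the first 1166 bp of macaque CYP1A2 CDS
# (resequencing of 63 M. fascicularis and 28 M. mulatta individuals).
# Counts are derived/reference chromosome counts per species.
position	ref	alt	functional_class	alt_count	ref_count	species
138	G	A	nonsense	0	126	M. fascicularis
286	A	del1	frameshift	4	122	M. fascicularis
1066	C	T	nonsense	8	118	M. fascicularis
1090	C	T	nonsense	2	124	M. fascicularis
1103	T	A	nonsense	11	115	M. fascicularis
138	G	A	nonsense	5	51	M. mulatta
286	A	del1	frameshift	0	56	M. mulatta
1066	C	T	nonsense	22	34	M. mulatta
1090	C	T	nonsense	0	56	M. mulatta
1103	T	A	nonsense	0	56	M. mulatta
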