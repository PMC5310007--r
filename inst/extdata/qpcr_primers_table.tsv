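gene	primer_sequences_5to3	product_size_bp
XLOC_957527	ACACGACCAGAACATCAGAATCACAGGAGAAGAGTAGG	162
XLOC_910648	TGCCATCCAGCCATCTCATCCACACACCACAGTTCCTTTACC	175
XLOC_1101518	CTCCTGGGCTACCGAATGTGCGGCTGTGAACTAAATGG	172
XLOC_1276445	TCGCTCCGTCTTCACCTACCGTTGCTCCATCACCCTTG	100
XLOC_2056339	CCTGTTGTTGGAATCACTCCTCTTATGCCTCGGATGG	184
XLOC_960044	CAAGGAGTCGCACGCTACCTCTTACGCCTCTGAATCGG	128
XLOC_032671	TGATGCCAAGAGGTAGCCTTATACAGACAGTGAAAGAGAGG	180
XLOC_688924	ATCTCCACTCTACAAACCTATACCACTCTCAAAGGGAAGCCAATG	142
Novel_000476	TTACCTACTACCATCCTTCACATCAGCAGAACCAGAACC	178
Novel_000453	GAAGTGTCGTCTGGAGATTACCTGTTGAGTGAGTCCTGTATTACC	181
CD38	CTACTGCCTTCTTCTGTGTTCTGCTTCTGGAATACG	185
GnRH1	CTAATCCTGCTGACTTTCTGTGACCTCTTTGGCTATCTCTTGG	127
beta-actin	CGTGACATCAAGGAGAAGGAAGGAAGGCTGGAAGAG	171
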