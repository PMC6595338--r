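gene	protein_change	n_patients	hla_alleles	n_neoantigens	n_icgc
BRCA2	I27V	1	B58:01C03:02C08:01	6	0
BRCA2	S37L	1	B15:02B58:01C03:02	6	1
BRCA2	V144F	1	B15:02C03:02	5	0
BRCA2	Q147R	1	A33:03	2	0
BRCA2	D156E	1	A11:01	1	0
BRCA2	N289H	1	A02:01C03:02	5	3
BRCA2	T2542M	1	C14:02	2	0
FAT4	Q453L	1	A02:01C03:02	12	5
FAT4	V462E	1	B40:01B58:01C03:02	11	0
FAT4	D598Y	1	A02:01B15:01	5	0
FAT4	A807V	1	A02:01B40:01B58:01C03:02	13	6
GNAQ	D95Y	1	A24:10B18:02B39:01C07:02	8	0
GNAQ	T96S	3	A02:01A03:01A11:01B15:01B39:01	25	10
LRP1B	H4368Q	1	A11:02	1	0
LRP1B	L1995M	1	C03:04	1	0
LRP1B	R3026S	1	A03:01B15:01	3	0
LRP1B	R4062K	1	A11:01A33:03C03:02	8	0
LRP1B	T2206I	1	A02:01	1	0
PIK3CA	G106C	1	A03:01A11:01	2	0
PIK3CA	H1047Y	1	B15:01	1	8
PIK3CA	V344M	1	A03:01A11:01C14:02	4	5
PREX2	E1428K	1	A30:01	2	0
PREX2	H895Q	1	B15:01C03:03	3	0
PREX2	Q102H	1	B15:01	1	0
PREX2	S1488L	1	A02:01A33:03B40:01C07:02	10	0
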