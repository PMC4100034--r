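codon	anticodon	copies	adat
TTT	AAA	0	0
TTC	GAA	12	0
TTA	TAA	4	0
TTG	CAA	7	0
TCT	AGA	11	1
TCC	GGA	0	0
TCA	TGA	5	0
TCG	CGA	4	0
TAT	ATA	1	0
TAC	GTA	14	0
TGT	ACA	0	0
TGC	GCA	30	0
TGG	CCA	9	0
CTT	AAG	9	1
CTC	GAG	0	0
CTA	TAG	3	0
CTG	CAG	11	0
CCT	AGG	10	1
CCC	GGG	0	0
CCA	TGG	7	0
CCG	CGG	4	0
CAT	ATG	0	0
CAC	GTG	11	0
CAA	TTG	11	0
CAG	CTG	20	0
CGT	ACG	7	1
CGC	GCG	0	0
CGA	TCG	6	0
CGG	CCG	4	0
ATT	AAT	14	1
ATC	GAT	3	0
ATA	TAT	5	0
ATG	CAT	20	0
ACT	AGT	10	1
ACC	GGT	0	0
ACA	TGT	6	0
ACG	CGT	6	0
AAT	ATT	0	0
AAC	GTT	32	0
AAA	TTT	16	0
AAG	CTT	17	0
AGT	ACT	0	1
AGC	GCT	8	0
AGA	TCT	6	0
AGG	CCT	5	0
GTT	AAC	11	1
GTC	GAC	0	0
GTA	TAC	7	0
GTG	CAC	16	0
GCT	AGC	25	1
GCC	GGC	0	0
GCA	TGC	9	0
GCG	CGC	4	0
GAT	ATC	0	0
GAC	GTC	19	0
GAA	TTC	8	0
GAG	CTC	8	0
GGT	ACC	0	0
GGC	GCC	15	0
GGA	TCC	9	0
GGG	CCC	7	0
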