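gene	transcript	cdna_change	protein_change	dbsnp_id	reported_class
ABCC9	NM_005691.3	3589C > T	R1197C	rs778849288	disease-causing
CACNA1C	NM_000719.6	6388G > A	D2130N	rs199473392	disease-causing
HCN4	NM_005477.2	2522C > T	S841L	rs200546024	disease-causing
KCNB2	NM_004770.2	1564G > A	E522K	rs745516217	disease-causing
KCNT1	NM_020822.2	3317G > A	R1106Q	rs561255614	disease-causing
PKP2	NM_004572.3	1093A > G	M365V	rs143900944	disease-causing
RANGRF	NM_016492.4	181G > T	E61*	rs140704891	disease-causing
SCN3B	NM_018400.3	328G > A	V110I	rs147205617	disease-causing
SCN5A	NM_198056.2	80G > A	R27H	rs199473045	disease-causing
SCN5A	NM_198056.2	677C > T	A226V	rs199473561	disease-causing
SCN5A	NM_198056.2	3068G > A	R1023H	rs199473592	disease-causing
SCN5A	NM_198056.2	3727G > A	D1243N	rs199473599	disease-causing
SCN5A	NM_198056.2	4018G > A	V1340I	rs199473605	disease-causing
SCN10A	NM_006514.3	41G > T	R14L	rs141207048	disease-causing
SCN10A	NM_006514.3	3803G > A	R1268Q	rs138832868	disease-causing
SCNN1A	NM_001038.5	1049G > A	R350Q	rs534158738	disease-causing
SLMAP	NM_007159.3	2129A > C	E710A	rs765326482	disease-causing
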