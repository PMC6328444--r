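variant	NFE	FIN	AMR	AFR	JEW	EAS	SAS	JPN3K	TWB
ABCC9|NM_005691|3589C>T	0.000024	0	0	0	0	0.001431	0.000032	0	0.002008
CACNA1C|NM_000719|6388G>A	0.000046	0	0	0	0.002504	0	0	0	0
HCN4|NM_005477|2522C>T	0.000058	0	0.000058	0.000085	0.001802	0	0	0	0
KCNB2|NM_004770|1564G>A	0.000024	0	0	0	0	0.001538	0	0.0013	0.001003
KCNT1|NM_020822|3317G>A	0.000062	0	0	0.000053	0	0.004356	0.000327	0.0027	0.004692
PKP2|NM_004572|1093A>G	0.000237	0	0	0	0	0	0.001137	0	0
RANGRF|NM_016492|181G>T	0.005406	0.01116	0.001018	0.000587	0.000297	0	0.001657	0	0
SCN3B|NM_018400|328G>A	0.000032	0	0.000029	0.000583	0	0.002438	0.000455	0.0025	0.003009
SCN5A|NM_198056|80G>A	0.000024	0	0.001569	0.000208	0	0.000159	0	0	0
SCN5A|NM_198056|677C>T	0.000008	0	0	0	0	0.001357	0	0	0.001508
SCN5A|NM_198056|3068G>A	0.000048	0	0.000174	0.000042	0	0.000053	0.001887	0	0
SCN5A|NM_198056|3727G>A	0.000024	0.000078	0.000116	0	0.002758	0.000053	0.000065	0.0001	0
SCN5A|NM_198056|4018G>A	0.000024	0	0	0.000042	0	0.000371	0.000065	0	0.001003
SCN10A|NM_006514|41G>T	0.002776	0.000931	0.000872	0.000375	0.009374	0	0.000162	0	0
SCN10A|NM_006514|3803G>A	0.003162	0.002957	0.000436	0.000542	0.000592	0.000319	0.000033	0.0001	0.000502
SCNN1A|NM_001038|1049G>A	0.000036	0.000066	0	0	0.000465	0.000033	0	0.001	0.001505
SLMAP|NM_007159|2129A>C	0	0	0	0	0	0.000988	0	0.0014	0
SCN5A|NM_198056|5770G>A	0.000016	0	0.000087	0	0.001084	0	0	0	0
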