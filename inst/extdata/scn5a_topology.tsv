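protein	start	end	domain
SCN5A	1	126	cytoplasmic
SCN5A	127	146	other-transmembrane
SCN5A	147	155	extracellular
SCN5A	156	180	other-transmembrane
SCN5A	181	189	cytoplasmic
SCN5A	190	208	other-transmembrane
SCN5A	209	212	extracellular
SCN5A	213	235	VSD
SCN5A	236	245	cytoplasmic
SCN5A	246	400	pore
SCN5A	401	711	cytoplasmic
SCN5A	712	730	other-transmembrane
SCN5A	731	738	extracellular
SCN5A	739	760	other-transmembrane
SCN5A	761	766	cytoplasmic
SCN5A	767	786	other-transmembrane
SCN5A	787	789	extracellular
SCN5A	790	812	VSD
SCN5A	813	827	cytoplasmic
SCN5A	828	940	pore
SCN5A	941	1200	cytoplasmic
SCN5A	1201	1221	other-transmembrane
SCN5A	1222	1229	extracellular
SCN5A	1230	1248	other-transmembrane
SCN5A	1249	1256	cytoplasmic
SCN5A	1257	1275	other-transmembrane
SCN5A	1276	1282	extracellular
SCN5A	1283	1305	VSD
SCN5A	1306	1319	cytoplasmic
SCN5A	1320	1480	pore
SCN5A	1481	1523	cytoplasmic
SCN5A	1524	1542	other-transmembrane
SCN5A	1543	1550	extracellular
SCN5A	1551	1572	other-transmembrane
SCN5A	1573	1580	cytoplasmic
SCN5A	1581	1600	other-transmembrane
SCN5A	1601	1607	extracellular
SCN5A	1608	1630	VSD
SCN5A	1631	1643	cytoplasmic
SCN5A	1644	1772	pore
SCN5A	1773	2016	cytoplasmic
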