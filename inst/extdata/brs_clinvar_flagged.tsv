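gene	transcript	cdna_change	protein_change	dbsnp_id	reported_class
SCN5A	NM_198056.2	5770G > A	A1924T	rs137854603	pathogenic
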