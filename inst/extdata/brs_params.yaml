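# Brugada syndrome disease parameters for the maximum credible allele
# frequency, and the population grouping used for ancestry restriction.
# East Asian prevalence ~0.12%; a single variant contributes at most 1%
# of genetic cases; penetrance 16% (the conservative end of the reported
# 16-32.7% co-segregation range). The applied cutoff of 0.001 relaxes
# the credible bound (7.5e-05) by more than a factor of 10 as a safety
# margin against excluding true pathogenic variants.
prevalence: 0.0012
allelic_contribution: 0.01
penetrance: 0.16
applied_cutoff: 0.001
grouping:
  Asian: [EAS, SAS, JEW, JPN3K, TWB]
  European: [NFE, FIN]
  American: [AMR]
  African: [AFR]
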