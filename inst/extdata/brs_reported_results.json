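{
  "max_credible_af": 0.000075,
  "n_flagged": 18,
  "n_asian_only": 14,
  "pct_flagged_overall": 4.1,
  "pct_scn5a_share": 87.5,
  "pct_non_scn5a": 21.8,
  "pct_scn5a": 1.6,
  "pct_radical": 0.9,
  "pct_missense": 5.6,
  "pct_hgmd": 4.2,
  "pct_clinvar": 1.5,
  "pct_cohort_variants": 0.45,
  "domain_tally_flagged_scn5a": {
    "VSD": 1,
    "pore": 1,
    "other-transmembrane": 1,
    "cytoplasmic": 3
  }
}
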