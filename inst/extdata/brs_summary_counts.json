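{
  "n_total": 440,
  "n_scn5a": 385,
  "n_hgmd": 405,
  "n_clinvar": 68,
  "n_overlap": 33,
  "n_nonsense": 40,
  "n_frameshift": 73,
  "n_splice": 23,
  "n_missense": 304,
  "n_cohort": 124,
  "n_cohort_carrier_patients": 5,
  "n_cohort_flagged_variants": 2,
  "n_cohort_subcutoff_variants": 10
}
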