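# Example pipeline configuration: one top-level section per module.
# Omitted entries fall back to the package defaults (see ?hgt_config).
search:
  matrix: BLOSUM62
  gap_open: 11
  gap_extend: 1
  lambda: 0.267
  K: 0.041
  max_evalue: 1.0e-3
hgt_index:
  bit_floor: 100
  hU_floor: 30
  ingroup: Fungi
cluster:
  threshold: 0.95
phylo:
  bootstrap_n: 100
  support_min: 0.7
  purity: 1.0
  max_per_search: 100
  max_evalue: 1.0e-10
events:
  min_prevalence: 0.5
amplicon:
  min_len: 200
  max_len: 380
  max_homopolymer: 8
  min_identity: 0.96
  min_coverage: 0.70
  novelty_radius: 0.04
cellulosome:
  min_identity: 0.2734
  dockerin_domain: CBM_10
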