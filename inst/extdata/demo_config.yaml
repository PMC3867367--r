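# Small demonstration configuration: a scaled-down synthetic screen
# (two short amplicons, shallow-ish depth) that runs in seconds.
seed: 11
thresholds:
  min_coverage: 400
  min_frequency: 0.005
pools:
  - {label: C109, n_individuals: 109, copies_per_individual: 4,
     max_siblings: 3, is_mutant: false}
  - {label: M109, n_individuals: 109, copies_per_individual: 4,
     max_siblings: 3, is_mutant: true}
  - {label: M754, n_individuals: 754, copies_per_individual: 4,
     max_siblings: 3, is_mutant: true}
simulate:
  amplicons:
    - {id: ampA, length: 1500}
    - {id: ampB, length: 900}
  wt_snp_per_bp: 0.0143
  ems_rate: 0.0002
  error_rate: 0.001
  depth_sdlog: 0.4
  mean_depth: {C109: 12000, M109: 12000, M754: 10000}
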