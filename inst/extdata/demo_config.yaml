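# Demo run: a small synthetic relapsing-remitting cohort with planted
# sex-specific differential expression and a mirror set.
seed: 7
n_permutations: 200
n_decoys: 100
synthetic:
  n_patients: 13
  n_controls: 13
  n_probes: 500
  frac_mirna: 0.5
  sex_ratio: 0.7
  n_de_relapse_f: 12
  n_de_remission_f: 12
  n_de_remission_m: 3
  n_mirror: 8
  effect_log2: 2
  patient_sd: 0.5
  noise_sd: 0.3
  detect_floor: 7
thresholds:
  p_cut: 0.001
  fdr_cut: 0.05
  min_sources: 3
  min_score: 40
  alpha: 0.05
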