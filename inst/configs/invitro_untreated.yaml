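# In vitro killing-assay mirror: untreated (proliferative PD-L1-/MHC-I-low)
# tumor cells at a 1:1 effector:target ratio.
experiment:
  mode: in_vitro
  n_tumor: 120
  n_tcell: 120
  frac_pd1_pos: 0.75
  frac_pdl1_pos: 0.0
  duration_h: 13.5
  replicates: 5
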