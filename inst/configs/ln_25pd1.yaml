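# 25% PD-1+ condition with the dendritic-cell / lymph-node supply enabled.
experiment:
  mode: tumor_bed
  n_tumor: 1200
  n_tcell: 12
  frac_pd1_pos: 0.25
  frac_pdl1_pos: 0.0
  placement: inside
  duration_h: 72
  replicates: 8
lymph_node:
  enabled: true
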