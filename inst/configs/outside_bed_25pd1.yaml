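# 25% PD-1+ T cells initialized uniformly outside the tumor-bed disc.
experiment:
  mode: tumor_bed
  n_tumor: 1200
  n_tcell: 12
  frac_pd1_pos: 0.25
  frac_pdl1_pos: 0.0
  placement: outside
  duration_h: 76
  replicates: 4
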