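# Adoptive-transfer condition: 1,200 tumor cells, 12 T cells (75% PD-1+,
# conventionally expanded product), T cells initialized inside the tumor bed.
experiment:
  mode: tumor_bed
  n_tumor: 1200
  n_tcell: 12
  frac_pd1_pos: 0.75
  frac_pdl1_pos: 0.0
  placement: inside
  duration_h: 72
  replicates: 4
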