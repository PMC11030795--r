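# Tumor-growth control: no T cells (calibration anchor for the doubling time).
experiment:
  mode: tumor_bed
  n_tumor: 1200
  n_tcell: 0
  frac_pd1_pos: 0.0
  frac_pdl1_pos: 0.0
  duration_h: 72
  replicates: 4
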