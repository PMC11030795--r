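# 25% PD-1+ condition with stochastic (rather than timer-based) refractory
# and exhaustion transitions: a smoother population phenotype shift.
experiment:
  mode: tumor_bed
  n_tumor: 1200
  n_tcell: 12
  frac_pd1_pos: 0.25
  frac_pdl1_pos: 0.0
  duration_h: 72
  replicates: 5
tcell:
  refractory_mode: probabilistic
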