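# Example astromap run configuration.
model:
  density: 32
  p: 1.5
  q: 2.1
  r: 1.4
  eta_A: 0.1
  eta_E: 0.3
  eta_I: 0.3
  rad_A: 0.27
  rad_I: 0.22
  settling_steps: 16
astrocyte:
  R_astro_mm: 0.1125
  gfap_scale: 2
  variant: full
  gap_junctions: false
homeostasis:
  beta: 0.991
  lambda: 0.01
  mu: 0.024
lgn:
  sigma_c: 0.0375
  sigma_s: 0.15
  gamma_o: 1
  gamma_s: 0.6
stimuli:
  sigma_major: 0.4
  sigma_minor: 0.09
  amplitude: 1
seed: 1
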