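# Thermodynamic consistency audit of the fixed-site staged-diffusion chain:
# detailed-balance cycle products and equal-bath uniformity.
model:
  type: multisite
protocol:
  type: zero_trans
  direction: influx
  grid:
    n_points: 12
fit:
  enabled: true
audit:
  enabled: true
  bath_conc: 10
seed: 1
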