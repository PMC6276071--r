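# Full kinetic characterisation of the default asymmetric carrier:
# zero-trans influx/efflux and equilibrium exchange fits plus derived ratios.
model:
  type: asymmetric
protocol:
  type: kinetic_summary
  grid:
    n_points: 24
audit:
  enabled: true
  bath_conc: 10
seed: 1
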