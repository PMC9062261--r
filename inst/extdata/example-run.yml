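# Example run configuration: 1% oxygen ischemia/reperfusion with metrics.
protocol:
  type: standard
  ischemicFraction: 0.01
solver:
  rtol: 1.0e-8
outputs:
  trajectory: true
  fluxes: true
  metrics: true
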