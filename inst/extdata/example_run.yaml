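# Example run configuration: a single HSP70-overexpression condition
# (40x) under high-intensity stimulation, with the shipped default
# parameterization.
protocol:
  synthesis_pulses:
    - {t_on: 0, duration: 10}
  activator_pulses:
    - {t_on: 50, duration: 15, amplitude: 0.5}
  hsp70_multiplier: 40
  t_end: 185
solver:
  output_dt: 0.5
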