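# Alzheimer regime: lam = 15.2, no landmark recognized, competition wandering
schema: navsim-scenario/1
map: default
start: 1
goal: 6
goal_code: 9
attention:
  default: 2.3
oscillator:
  lam: 15.2
  B: 1.5
  As: 1
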