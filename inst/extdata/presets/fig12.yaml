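# Healthy navigation: start LM1 (initially perceived code 4.2), goal LM6
schema: navsim-scenario/1
map: default
start: 1
goal: 6
here_code: 4.2
goal_code: 9
attention:
  default: 2.3
oscillator:
  lam: 0.2
  B: 1.5
  As: 1
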