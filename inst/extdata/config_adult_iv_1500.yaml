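# Example run configuration: 1500 mg IV infusion (0.75 h) in the adult
# reference subject.
compound: levetiracetam
physiology:
  type: adult
  weight: 64.19
  height: 1.70
  age: 23.71
  sex: M
regimen:
  route: iv_infusion
  dose: 1500
  duration: 0.75
  t_end: 48
simulation:
  dt: 0.05
seed: 1
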