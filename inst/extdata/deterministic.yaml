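# Four-program reallocation with known costs (thousand USD) and effects
# (life years): program a is displaced by A; B is cancelled in favour of b.
programs:
  A: {label: "Program A", cost: 100000, effect: 150}
  a: {label: "Program a", cost: 40000, effect: 90}
  B: {label: "Program B", cost: 140000, effect: 50}
  b: {label: "Program b", cost: 70000, effect: 30}
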