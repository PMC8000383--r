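# Mirror of variance_decreasing.yaml: the newly funded portfolio {A, b}
# carries the larger standard deviations, so the reallocation increases
# portfolio risk while leaving the net-outcome distribution unchanged.
programs:
  A: {label: "Program A", mean_cost: 100000, sd_cost: 13000, mean_effect: 150, sd_effect: 13, rho: 0.5}
  a: {label: "Program a", mean_cost: 40000, sd_cost: 5000, mean_effect: 90, sd_effect: 5, rho: 0.5}
  B: {label: "Program B", mean_cost: 140000, sd_cost: 5000, mean_effect: 50, sd_effect: 5, rho: 0.5}
  b: {label: "Program b", mean_cost: 70000, sd_cost: 13000, mean_effect: 30, sd_effect: 13, rho: 0.5}
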