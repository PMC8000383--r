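# Stochastic scenario in which the newly funded portfolio {A, b} carries
# the smaller standard deviations: the reallocation reduces portfolio risk.
# Costs in thousand USD, effects in life years; rho is the within-program
# cost-effect correlation (programs are independent of one another).
programs:
  A: {label: "Program A", mean_cost: 100000, sd_cost: 5000, mean_effect: 150, sd_effect: 5, rho: 0.5}
  a: {label: "Program a", mean_cost: 40000, sd_cost: 13000, mean_effect: 90, sd_effect: 13, rho: 0.5}
  B: {label: "Program B", mean_cost: 140000, sd_cost: 13000, mean_effect: 50, sd_effect: 13, rho: 0.5}
  b: {label: "Program b", mean_cost: 70000, sd_cost: 5000, mean_effect: 30, sd_effect: 5, rho: 0.5}
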