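# Default run configuration: 7.4 GBq per cycle, 6 planned cycles (44.4 GBq).
nuclide:
  name: Lu-177
  half_life_h: 159.528
injected_GBq_per_cycle: 7.4
planned_cycles: 6
at_risk_organs:
  - kidneys
  - lacrimal_glands
  - salivary_glands
  - red_marrow
tia_mode: analytic
sphere:
  mass_g: 0.7
  absorbed_fraction: 0.90
marrow:
  rmblr: 1.0
  mass_g: 1170
m_comparisons: 5
seed: 1
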