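# Equivalence factors (w_j): physical area -> world-average-productivity area.
# Yield factors (y_j): local vs world-average productivity, supply side only;
# fossil-energy (CO2-absorption) land gets 0 because no land is actually set
# aside to absorb CO2. 12% of capacity is reserved for biodiversity.
equivalence_factor:
  arable: 2.51
  forest: 1.26
  pasture: 0.46
  water: 0.37
  fossil_energy: 1.26
  built_up: 2.51
yield_factor:
  arable: 1.66
  pasture: 0.19
  forest: 0.91
  built_up: 1.66
  water: 1.00
  fossil_energy: 0
biodiversity_fraction: 0.12
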