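# Hypothetical 2x2 design with a steep variance gradient across cells and an
# interaction effect of 2, evaluated under six unit-cost patterns chosen to
# span cheap-to-expensive orderings in both directions.
design:
  means: [1, 0, 0, 1]
  variances: [1, 4, 9, 16]
  contrasts: [interaction]
  null_value: 0
  alpha: 0.05
  target_power: 0.8
cost:
  overhead: 0
  unit_costs:
    equal: [1, 1, 1, 1]
    rising: [1, 2, 3, 4]
    falling: [4, 3, 2, 1]
    late_heavy: [1, 1, 2, 5]
    early_heavy: [5, 2, 1, 1]
    inner_heavy: [1, 3, 3, 1]
methods: [proposed, luh_guo]
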