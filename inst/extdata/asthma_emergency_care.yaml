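# Planning values for a 2x2 asthma emergency-care study: factor A is attack
# recency (recent / stable), factor B is panic-fear level (low / high), the
# response is service cost on a transformed scale. Cell order (1,1), (1,2),
# (2,1), (2,2). The "varied" unit costs reflect per-subject recruitment cost
# differences across cells; "equal" makes total cost equal total sample size.
design:
  means: [1.23, 0.42, 0.13, 0.38]
  variances: [0.6889, 0.5184, 0.1156, 0.5929]
  contrasts: [interaction, mainA, mainB]
  null_value: 0
  alpha: 0.05
  target_power: 0.8
cost:
  overhead: 0
  unit_costs:
    varied: [784.74, 267.96, 82.94, 242.44]
    equal: [1, 1, 1, 1]
methods: [proposed, luh_guo]
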