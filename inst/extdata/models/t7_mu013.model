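# T7 circuit, faster effective growth (mu = 0.013).
species: ["n", "m"]
parameters: {M: 10, k_0: 0.0011, k_1: 0.0087, k_f: 0.01, k_b: 0.11, d_x0: 0.003, mu: 0.013, theta: 1}
bounds: {"n": 120, "m": 10}
scale: 1
reactions:
  - name: synth_O0
    propensity: k_0 * m
    change: {"n": 1}
  - name: synth_O1
    propensity: k_1 * (M - m)
    change: {"n": 1}
  - name: activate
    propensity: k_f * m * n
    change: {"n": -1, "m": -1}
  - name: deactivate
    propensity: k_b * (M - m)
    change: {"n": 1, "m": 1}
  - name: degrade
    propensity: d_x0 * n
    change: {"n": -1}
  - name: divide
    propensity: mu / (1 + n / theta)
    kernel: t7_division
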