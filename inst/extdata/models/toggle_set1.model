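# Toggle switch, reference parameter set 1 (asymmetric).
species: [u, v]
parameters: {K_u: 1, K_v: 1, r_u: 10, r_v: 9, beta: 2, gamma: 2, d_u: 1, d_v: 1}
bounds: {u: 60, v: 60}
scale: 1
reactions:
  - name: synth_u
    propensity: r_u / (1 + (v / K_v)^beta)
    change: {u: 1}
  - name: degr_u
    propensity: d_u * u
    change: {u: -1}
  - name: synth_v
    propensity: r_v / (1 + (u / K_u)^gamma)
    change: {v: 1}
  - name: degr_v
    propensity: d_v * v
    change: {v: -1}
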