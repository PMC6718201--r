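# Synthetic example: unit-cell prior
a_A: 35
b_A: 45
c_A: 60
alpha_deg: 85
beta_deg: 95
gamma_deg: 100
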