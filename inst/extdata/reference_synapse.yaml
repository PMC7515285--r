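p1: 0.5
q1: 0.05
pmax: 1.0
qmax: 0.2
u: 0.5
v: 0.5
alpha: 0.3
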