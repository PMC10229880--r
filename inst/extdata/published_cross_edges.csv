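node_a,node_b,weight
A1,IGD3,0.04
A1,IGD5,0.02
A1,IGD9,0.01
A2,IGD1,0.04
A2,IGD2,0.04
A2,IGD3,0.06
A2,IGD4,0.01
A2,IGD6,0.04
A2,IGD8,0.02
A3,IGD5,0.12
A3,IGD6,0.06
A3,IGD7,0.02
A3,IGD9,0.01
A4,IGD5,0.01
A5,IGD1,0.003
A5,IGD4,0.03
A5,IGD5,0.06
A5,IGD6,0.03
A5,IGD8,0.01
A5,IGD9,0.04
A1,IGD6,-0.01
A4,IGD6,-0.03
A4,IGD8,-0.02
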