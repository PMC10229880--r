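node,community,mean,sd
A1,anxiety,3.69,2.43
A2,anxiety,3.32,2.35
A3,anxiety,1.05,1.84
A4,anxiety,2.70,2.29
A5,anxiety,2.97,2.50
IGD1,IGD,1.69,1.05
IGD2,IGD,1.78,1.08
IGD3,IGD,1.38,0.83
IGD4,IGD,1.50,0.89
IGD5,IGD,1.33,0.81
IGD6,IGD,1.38,0.82
IGD7,IGD,1.52,1.00
IGD8,IGD,1.50,0.95
IGD9,IGD,1.50,0.99
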