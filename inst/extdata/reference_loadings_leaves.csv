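element,PC1,PC2,PC3,PC4,communality
K,0.85,0.006,0.172,-0.106,0.764
Al,0.83,0.289,0.067,-0.058,0.78
Si,0.78,0.118,-0.296,-0.1,0.72
Cl,0.645,0.07,0.319,0.028,0.523
Cr,0.096,0.941,0.106,0.028,0.906
Fe,0.205,0.889,0.048,0.203,0.876
Mn,0.024,0.5,0.249,0.034,0.314
P,0.029,0.22,0.853,-0.084,0.784
S,0.141,0.215,0.778,-0.15,0.693
Mg,0.583,-0.2,0.584,0.096,0.731
Zn,-0.125,0.243,0.235,0.831,0.82
Pb,-0.098,-0.251,-0.366,0.725,0.731
Ti,0.039,0.413,-0.25,0.665,0.677
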