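element,PC1,PC2,PC3,communality
Mn,0.965,0.088,0.145,0.96
Cr,0.96,0.068,0.185,0.96
Fe,0.856,0.437,0.154,0.946
Mg,0.74,0.327,0.077,0.661
Si,0.277,0.902,0.005,0.891
Al,0.347,0.871,-0.026,0.88
Ti,0.259,0.817,0.027,0.735
K,-0.422,0.658,0.12,0.625
S,0.236,0.307,0.734,0.689
Zn,0.474,0.044,0.606,0.594
Pb,-0.034,-0.124,0.579,0.351
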