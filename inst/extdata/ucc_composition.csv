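element,mg_per_kg
Al,81500
Si,311400
Fe,39200
Ca,25700
Mg,14900
K,23200
Ti,3840
P,655
Mn,775
S,621
Cl,370
As,4.8
Ba,628
Br,1.6
Cr,92
Cu,28
Pb,17
Rb,84
Se,0.09
Sr,320
Zn,67
Zr,193
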