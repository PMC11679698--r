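biomonitor,component,pct_variance
strawberry_leaf,PC1,29.2
strawberry_leaf,PC2,18.8
strawberry_leaf,PC3,14.3
strawberry_leaf,PC4,9.4
lichen,PC1,46.5
lichen,PC2,19.3
lichen,PC3,9.6
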