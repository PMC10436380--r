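ontology,richness,lawfulness,clarity,consistency,interpretability,comprehensiveness
DEVO,0.564,1,0.988,1,0.964,0.02
DL,0.333,0.501,0.999,0.0004,1,0.22
HDDO,0.154,1,0.998,0.934,0.901,0.065
SPO,0.385,1,0.983,0.981,0.575,0.006
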