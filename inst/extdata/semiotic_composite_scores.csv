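metric,DEVO,DL,HDDO,SPO
syntactic,0.782,0.417,0.577,0.692
semantic,0.986,0.669,0.946,0.848
pragmatic,0.02,0.22,0.065,0.006
overall,0.597,0.436,0.53,0.516
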