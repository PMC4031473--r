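>E2F1_consensus_synthetic
A [   5   5   5   7   7   5   5   5 ]
C [   5   5   5  43  43  85   5  85 ]
G [   5   5   5  43  43   5  85   5 ]
T [  85  85  85   7   7   5   5   5 ]
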