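fibroblast	A11.329.228
human periodontal ligament cell	A11.329.228.900
t-cell	A11.118.637.555.567
neuron	A11.671
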