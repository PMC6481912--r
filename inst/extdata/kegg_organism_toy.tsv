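mouse	B01.050.199
transgenic mouse	B01.050.199.550
rat	B01.050.210
human	B01.050.116
caenorhabditis elegans	B01.500.500.294
drosophila melanogaster	B01.500.131.365
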