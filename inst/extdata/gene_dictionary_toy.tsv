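hsf-1	nr5a1
nephrin	nphs1
podocin	nphs2
tau	mapt
tdp-43	tardbp
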